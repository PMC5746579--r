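#' Reconstruct a planar velocity field in a horizontal layer
#'
#' Solvent samples with |z - z_c| <= thickness/2, pooled over the time
#' window, are assigned to a regular `n_cells x n_cells` grid covering the
#' periodic x,y box; each cell stores the mean (v_x, v_y) and sample count.
#' Cells empty after pooling are filled by inverse-distance weighting from
#' the 4 nearest sampled cells (periodic distance) and flagged.
#'
#' @param traj a `glyco_trajectory`.
#' @param z_c layer centre height.
#' @param thickness slab thickness (default 2 length units).
#' @param n_cells grid cells per side.
#' @param window `c(t1, t2)` averaging window or `NULL` for all frames.
#' @return a `glyco_field2d`: list with `xe, ye` (edges), matrices
#'   `vx, vy, count`, logical `filled`, and metadata.
#' @export
grid_field <- function(traj, z_c, thickness = 2, n_cells = 24, window = NULL) {
  stopifnot(inherits(traj, "glyco_trajectory"))
  if (z_c - thickness / 2 < 0 || z_c + thickness / 2 > traj$box[3])
    stop("slab extends outside the box")
  keep <- frames_in_window(traj, window)
  Lx <- traj$box[1]; Ly <- traj$box[2]
  sidx <- solvent_idx(traj)
  sx <- matrix(0, n_cells, n_cells); sy <- matrix(0, n_cells, n_cells)
  ct <- matrix(0L, n_cells, n_cells)
  for (k in keep) {
    fr <- traj$frames[[k]]
    z <- fr$pos[sidx, 3]
    inz <- abs(z - z_c) <= thickness / 2
    if (!any(inz)) next
    px <- fr$pos[sidx, 1][inz] %% Lx
    py <- fr$pos[sidx, 2][inz] %% Ly
    ix <- pmin(n_cells, floor(px / Lx * n_cells) + 1L)
    iy <- pmin(n_cells, floor(py / Ly * n_cells) + 1L)
    cell <- (iy - 1L) * n_cells + ix
    vxs <- rowsum(fr$vel[sidx, 1][inz], cell)
    vys <- rowsum(fr$vel[sidx, 2][inz], cell)
    ids <- as.integer(rownames(vxs))
    sx[ids] <- sx[ids] + vxs[, 1]
    sy[ids] <- sy[ids] + vys[, 1]
    ct[ids] <- ct[ids] + tabulate(cell, nbins = n_cells * n_cells)[ids]
  }
  empty <- ct == 0
  if (mean(empty) > 0.5)
    stop(sprintf("%.0f%% of cells empty: use a coarser grid or longer window",
                 100 * mean(empty)))
  vx <- ifelse(empty, NA, sx / pmax(ct, 1))
  vy <- ifelse(empty, NA, sy / pmax(ct, 1))
  filled <- empty
  if (any(empty)) {
    cx <- (seq_len(n_cells) - 0.5) * Lx / n_cells
    cy <- (seq_len(n_cells) - 0.5) * Ly / n_cells
    sampled <- which(!empty, arr.ind = TRUE)
    spx <- cx[sampled[, 1]]; spy <- cy[sampled[, 2]]
    for (e in which(empty)) {
      i <- (e - 1L) %% n_cells + 1L; j <- (e - 1L) %/% n_cells + 1L
      dx <- abs(cx[i] - spx); dx <- pmin(dx, Lx - dx)
      dy <- abs(cy[j] - spy); dy <- pmin(dy, Ly - dy)
      d2 <- dx^2 + dy^2
      near <- order(d2)[seq_len(min(4, length(d2)))]
      w <- 1 / pmax(d2[near], 1e-12)
      sel <- cbind(sampled[near, 1], sampled[near, 2])
      vx[i, j] <- sum(w * vx[sel]) / sum(w)
      vy[i, j] <- sum(w * vy[sel]) / sum(w)
    }
  }
  out <- list(xe = seq(0, Lx, length.out = n_cells + 1),
              ye = seq(0, Ly, length.out = n_cells + 1),
              vx = vx, vy = vy, count = ct, filled = filled,
              z_c = z_c, thickness = thickness, box = traj$box,
              window = if (is.null(window)) range(traj$times) else window)
  class(out) <- "glyco_field2d"
  out
}

#' Construct a `glyco_field2d` from matrices (for analytic test fields)
#'
#' @param vx,vy velocity matrices (cell means, x index first).
#' @param Lx,Ly box extent covered by the grid.
#' @return a `glyco_field2d`.
#' @export
field2d_from_matrices <- function(vx, vy, Lx, Ly) {
  n <- nrow(vx)
  out <- list(xe = seq(0, Lx, length.out = n + 1),
              ye = seq(0, Ly, length.out = ncol(vx) + 1),
              vx = vx, vy = vy, count = matrix(1L, n, ncol(vx)),
              filled = matrix(FALSE, n, ncol(vx)), z_c = NA, thickness = NA,
              box = c(Lx, Ly, NA), window = c(NA, NA))
  class(out) <- "glyco_field2d"
  out
}

field_centres <- function(field) {
  list(x = (field$xe[-1] + field$xe[-length(field$xe)]) / 2,
       y = (field$ye[-1] + field$ye[-length(field$ye)]) / 2)
}

# bilinear interpolation on the periodic cell-centre grid
interp_field <- function(field, x, y) {
  nx <- nrow(field$vx); ny <- ncol(field$vx)
  Lx <- field$xe[length(field$xe)]; Ly <- field$ye[length(field$ye)]
  hx <- Lx / nx; hy <- Ly / ny
  gx <- (x %% Lx) / hx - 0.5
  gy <- (y %% Ly) / hy - 0.5
  i0 <- floor(gx); j0 <- floor(gy)
  fx <- gx - i0; fy <- gy - j0
  i0 <- (as.integer(i0) %% nx + nx) %% nx + 1L
  j0 <- (as.integer(j0) %% ny + ny) %% ny + 1L
  i1 <- i0 %% nx + 1L; j1 <- j0 %% ny + 1L
  bil <- function(m)
    m[i0, j0] * (1 - fx) * (1 - fy) + m[i1, j0] * fx * (1 - fy) +
    m[i0, j1] * (1 - fx) * fy + m[i1, j1] * fx * fy
  c(bil(field$vx), bil(field$vy))
}

#' Default region of interest
#'
#' Central rectangle holding 50% of the box area (side scale 1/sqrt(2)).
#' @param field a `glyco_field2d`.
#' @return `c(x_min, x_max, y_min, y_max)`.
#' @export
default_roi <- function(field) {
  Lx <- field$xe[length(field$xe)]; Ly <- field$ye[length(field$ye)]
  s <- sqrt(0.5)
  c(Lx * (1 - s) / 2, Lx * (1 + s) / 2, Ly * (1 - s) / 2, Ly * (1 + s) / 2)
}

#' Integrate streamlines through a planar field
#'
#' Fixed-step 4th-order Runge-Kutta advection through the bilinearly
#' interpolated field; step length `step_frac` times the cell width.
#' Termination: leaving the region of interest, reaching `max_steps`, or
#' local speed below `1e-6` times the field RMS speed (stagnation).
#'
#' @param field a complete `glyco_field2d` (no unfilled empty cells).
#' @param seeds 2-column matrix of seed points, or `NULL` for a uniform
#'   grid of cell centres inside the ROI.
#' @param step_frac RK4 step as a fraction of the cell width.
#' @param max_steps maximum steps per streamline.
#' @param roi `c(x_min, x_max, y_min, y_max)`; default central 50% area.
#' @return a `glyco_streamlines`: list with `lines` (list of vertex
#'   matrices) and `summary` (seed, arc length, termination reason).
#' @export
integrate_streamlines <- function(field, seeds = NULL, step_frac = 0.25,
                                  max_steps = 10000, roi = NULL) {
  stopifnot(inherits(field, "glyco_field2d"))
  if (anyNA(field$vx) || anyNA(field$vy))
    stop("field has unfilled empty cells")
  if (is.null(roi)) roi <- default_roi(field)
  cc <- field_centres(field)
  if (is.null(seeds)) {
    gx <- cc$x[cc$x >= roi[1] & cc$x <= roi[2]]
    gy <- cc$y[cc$y >= roi[3] & cc$y <= roi[4]]
    seeds <- as.matrix(expand.grid(x = gx, y = gy))
  }
  seeds <- matrix(as.numeric(seeds), ncol = 2)
  inside <- function(p) p[1] >= roi[1] && p[1] <= roi[2] &&
    p[2] >= roi[3] && p[2] <= roi[4]
  bad <- which(!apply(seeds, 1, inside))
  if (length(bad))
    stop("seed(s) outside the ROI: ",
         paste(sprintf("(%g, %g)", seeds[bad, 1], seeds[bad, 2]), collapse = " "))
  h <- step_frac * (field$xe[2] - field$xe[1])
  vrms <- sqrt(mean(field$vx^2 + field$vy^2))
  stagn <- 1e-6 * vrms
  lines <- vector("list", nrow(seeds))
  lens <- numeric(nrow(seeds))
  term <- character(nrow(seeds))
  for (s in seq_len(nrow(seeds))) {
    p <- seeds[s, ]
    verts <- matrix(NA_real_, max_steps + 1L, 2)
    verts[1, ] <- p
    len <- 0; reason <- "max-steps"; nv <- 1L
    for (st in seq_len(max_steps)) {
      v1 <- interp_field(field, p[1], p[2])
      sp <- sqrt(sum(v1^2))
      if (!is.finite(sp) || sp == 0 || sp < stagn) {
        reason <- "stagnation"
        break
      }
      d1 <- v1 / sp
      k2 <- interp_field(field, p[1] + h / 2 * d1[1], p[2] + h / 2 * d1[2])
      d2 <- k2 / max(sqrt(sum(k2^2)), stagn)
      k3 <- interp_field(field, p[1] + h / 2 * d2[1], p[2] + h / 2 * d2[2])
      d3 <- k3 / max(sqrt(sum(k3^2)), stagn)
      k4 <- interp_field(field, p[1] + h * d3[1], p[2] + h * d3[2])
      d4 <- k4 / max(sqrt(sum(k4^2)), stagn)
      step <- h / 6 * (d1 + 2 * d2 + 2 * d3 + d4)
      pn <- p + step
      nv <- nv + 1L
      verts[nv, ] <- pn
      len <- len + sqrt(sum(step^2))
      p <- pn
      if (!inside(p)) { reason <- "boundary"; break }
    }
    lines[[s]] <- verts[seq_len(nv), , drop = FALSE]
    lens[s] <- len
    term[s] <- reason
  }
  out <- list(lines = lines,
              summary = data.frame(seed_x = seeds[, 1], seed_y = seeds[, 2],
                                   length = lens, termination = term))
  class(out) <- "glyco_streamlines"
  out
}

#' Planar vorticity field
#'
#' \eqn{\omega_z = \partial v_y / \partial x - \partial v_x / \partial y}
#' by central differences on the cell-centre grid, with periodic wrap at
#' the grid edges (the simulated box is periodic in x, y). For a linear
#' field the interior values are exact.
#'
#' @param field a complete `glyco_field2d` of at least 3 x 3 cells.
#' @return matrix of omega_z (1/time units).
#' @export
vorticity <- function(field) {
  nx <- nrow(field$vx); ny <- ncol(field$vx)
  if (nx < 3 || ny < 3) stop("grid must be at least 3 x 3")
  if (anyNA(field$vx) || anyNA(field$vy)) stop("field has missing cells")
  hx <- field$xe[2] - field$xe[1]; hy <- field$ye[2] - field$ye[1]
  ip <- c(2:nx, 1); im <- c(nx, 1:(nx - 1))
  jp <- c(2:ny, 1); jm <- c(ny, 1:(ny - 1))
  (field$vy[ip, ] - field$vy[im, ]) / (2 * hx) -
    (field$vx[, jp] - field$vx[, jm]) / (2 * hy)
}

#' Empirical probability density with convergence trace
#'
#' Histogram density on a shared support, with a convergence check: the
#' density is recomputed from the first `fractions` of the sample and the
#' L1 distance between successive curves is recorded; the curve is flagged
#' converged when the final successive distance is below 0.05.
#'
#' @param samples numeric vector (>= 20 values).
#' @param n_bins number of histogram bins.
#' @param fractions increasing sample fractions for the convergence trace.
#' @return a `glyco_pdf` data.frame `support, density` with attributes
#'   `n`, `converged`, `l1_trace`.
#' @export
pdf_curve <- function(samples, n_bins = 30,
                      fractions = c(0.25, 0.5, 0.75, 1)) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 20) stop("need at least 20 samples")
  rng <- range(samples)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bw <- br[2] - br[1]
  dens <- function(x) {
    h <- graphics::hist(x, breaks = br, plot = FALSE)
    h$density
  }
  curves <- lapply(fractions, function(f)
    dens(samples[seq_len(max(1, floor(f * length(samples))))]))
  l1 <- vapply(seq_len(length(curves) - 1), function(i)
    sum(abs(curves[[i + 1]] - curves[[i]])) * bw, numeric(1))
  out <- data.frame(support = (br[-1] + br[-(n_bins + 1)]) / 2,
                    density = curves[[length(curves)]])
  attr(out, "n") <- length(samples)
  attr(out, "converged") <- if (length(l1)) l1[length(l1)] < 0.05 else TRUE
  attr(out, "l1_trace") <- l1
  class(out) <- c("glyco_pdf", "data.frame")
  out
}

#' Exceedance probability of |samples| over thresholds
#'
#' @param samples numeric vector.
#' @param thresholds numeric thresholds.
#' @return data.frame `threshold, prob` with P(|x| > threshold).
#' @export
abs_exceedance <- function(samples, thresholds) {
  samples <- samples[is.finite(samples)]
  data.frame(threshold = thresholds,
             prob = vapply(thresholds,
                           function(th) mean(abs(samples) > th), numeric(1)))
}
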