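#' Partition the ectodomain into near-wall / dendritic / flow regions
#'
#' The three stacked z-intervals above the wall surface used for all
#' regional statistics: near-wall ("wg"), dendritic ("d") and flow ("f").
#' `bounds` are cumulative upper bounds measured from the wall surface `z0`
#' (defaults 12, 36, 50 length units); the intervals are half-open
#' `[lower, upper)`.
#'
#' @param z0 wall surface height.
#' @param bounds increasing cumulative upper bounds of wg, d, f above `z0`.
#' @return an object of class `glyco_regions`.
#' @examples
#' reg <- partition_regions(0)
#' region_of(c(5, 20, 40, 50), reg)  # "wg" "d" "f" NA
#' @export
partition_regions <- function(z0 = 0, bounds = c(12, 36, 50)) {
  if (length(bounds) != 3 || any(diff(bounds) <= 0) || bounds[1] <= 0)
    stop("bounds must be three strictly increasing positive values")
  reg <- list(z0 = z0, z_wg = bounds[1], z_d = bounds[2], z_f = bounds[3],
              names = c("wg", "d", "f"))
  class(reg) <- "glyco_regions"
  reg
}

#' @rdname partition_regions
#' @param z numeric vector of heights.
#' @param regions a `glyco_regions`.
#' @export
region_of <- function(z, regions) {
  lo <- regions$z0
  breaks <- lo + c(0, regions$z_wg, regions$z_d, regions$z_f)
  idx <- findInterval(z, breaks, left.open = FALSE, rightmost.closed = FALSE)
  out <- rep(NA_character_, length(z))
  inside <- idx >= 1 & idx <= 3 & z < breaks[4]
  out[inside] <- regions$names[idx[inside]]
  out
}

#' @export
print.glyco_regions <- function(x, ...) {
  cat(sprintf("regions above z0 = %g: wg [%g, %g), d [%g, %g), f [%g, %g)\n",
              x$z0, x$z0, x$z0 + x$z_wg, x$z0 + x$z_wg, x$z0 + x$z_d,
              x$z0 + x$z_d, x$z0 + x$z_f))
  invisible(x)
}

frames_in_window <- function(traj, window) {
  if (is.null(window)) return(seq_along(traj$times))
  keep <- which(traj$times >= window[1] & traj$times <= window[2])
  if (length(keep) == 0) stop("empty time window [", window[1], ", ",
                              window[2], "]")
  keep
}

zbin_index <- function(z, z0, ztop, n_bins) {
  h <- (ztop - z0) / n_bins
  idx <- floor((z - z0) / h) + 1L
  idx[z == ztop] <- n_bins  # clamp a sample exactly at the top
  idx[z < z0 | z > ztop] <- NA_integer_
  as.integer(idx)
}

#' Time-averaged vertical velocity profile of an x-slice
#'
#' For every frame in the window, solvent beads whose periodic-aware x
#' distance to `x_centre` is at most `slice_width / 2` are assigned to
#' `n_bins` equal z-bins spanning the ectodomain `[z0, z0 + z_f)`; v_x is
#' averaged pooling all (bead, frame) samples per bin. Bins with zero
#' samples are flagged missing (NA), never zero.
#'
#' @param traj a `glyco_trajectory`.
#' @param regions a `glyco_regions` (defines the binned z-extent).
#' @param x_centre slice centreline; `NULL` selects the whole x extent
#'   ("whole ectodomain" profile).
#' @param slice_width slice width in x (default 2 length units).
#' @param n_bins number of equal z-bins (default 25).
#' @param window `c(t1, t2)` averaging window, or `NULL` for all frames.
#' @return a `glyco_profile` data.frame with columns `z_lo, z_hi, z_mid,
#'   mean_vx, count`.
#' @export
slice_profile <- function(traj, regions, x_centre = NULL, slice_width = 2,
                          n_bins = 25, window = NULL) {
  stopifnot(inherits(traj, "glyco_trajectory"), inherits(regions, "glyco_regions"))
  if (!is.null(x_centre) && slice_width > traj$box[1])
    stop("slice width exceeds the periodic box length")
  keep <- frames_in_window(traj, window)
  z0 <- regions$z0; ztop <- regions$z0 + regions$z_f
  sidx <- solvent_idx(traj)
  sums <- numeric(n_bins); counts <- integer(n_bins)
  Lx <- traj$box[1]
  for (k in keep) {
    p <- traj$frames[[k]]$pos[sidx, , drop = FALSE]
    v <- traj$frames[[k]]$vel[sidx, 1]
    if (!is.null(x_centre)) {
      dx <- p[, 1] - x_centre
      dx <- dx - Lx * round(dx / Lx)
      inx <- abs(dx) <= slice_width / 2
      p <- p[inx, , drop = FALSE]; v <- v[inx]
    }
    bi <- zbin_index(p[, 3], z0, ztop, n_bins)
    ok <- !is.na(bi)
    if (!any(ok)) next
    sk <- rowsum(v[ok], bi[ok])
    sums[as.integer(rownames(sk))] <- sums[as.integer(rownames(sk))] + sk[, 1]
    counts <- counts + tabulate(bi[ok], nbins = n_bins)
  }
  edges <- seq(z0, ztop, length.out = n_bins + 1)
  out <- data.frame(z_lo = edges[-(n_bins + 1)], z_hi = edges[-1],
                    z_mid = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                    mean_vx = ifelse(counts > 0, sums / pmax(counts, 1), NA),
                    count = counts)
  attr(out, "window") <- if (is.null(window)) range(traj$times) else window
  attr(out, "slice") <- if (is.null(x_centre)) "whole ectodomain" else
    sprintf("x = %g +/- %g", x_centre, slice_width / 2)
  class(out) <- c("glyco_profile", "data.frame")
  out
}

#' Temporal contour of layer-mean velocities
#'
#' Slices the ectodomain into `n_layers` equal sub-layers and, at every
#' cadence tick (nearest recorded frame), reports the layer-mean solvent
#' v_x over the full x,y extent. Empty layers are NA.
#'
#' @inheritParams slice_profile
#' @param n_layers number of z-layers (>= 2).
#' @param cadence tick spacing in time units (>= frame spacing); `NULL`
#'   uses every recorded frame.
#' @return matrix `v[z_layer, t]` with attributes `times` and `edges`.
#' @export
temporal_contour <- function(traj, regions, n_layers = 25, cadence = NULL) {
  if (n_layers < 2) stop("n_layers must be >= 2")
  tt <- traj$times
  if (is.null(cadence)) {
    ticks <- tt
  } else {
    if (length(tt) > 1 && cadence < min(diff(tt)) - 1e-12)
      stop("cadence finer than the frame spacing")
    ticks <- seq(tt[1], tt[length(tt)], by = cadence)
  }
  fidx <- vapply(ticks, function(t) which.min(abs(tt - t)), integer(1))
  z0 <- regions$z0; ztop <- regions$z0 + regions$z_f
  sidx <- solvent_idx(traj)
  m <- matrix(NA_real_, n_layers, length(ticks))
  for (c in seq_along(fidx)) {
    fr <- traj$frames[[fidx[c]]]
    bi <- zbin_index(fr$pos[sidx, 3], z0, ztop, n_layers)
    ok <- !is.na(bi)
    if (!any(ok)) next
    means <- tapply(fr$vel[sidx, 1][ok], bi[ok], mean)
    m[as.integer(names(means)), c] <- means
  }
  attr(m, "times") <- tt[fidx]
  attr(m, "edges") <- seq(z0, ztop, length.out = n_layers + 1)
  m
}

#' Per-frame regional mean velocities
#'
#' For each recorded frame, the mean solvent v_x within each of the wg/d/f
#' regions, plus per-region dispersion summaries (inter-frame standard
#' deviation and central 95% width) reproducing the fluctuation-width
#' contrast between regions. A region empty of solvent in some frame is
#' flagged NA for that frame.
#'
#' @inheritParams slice_profile
#' @return a `glyco_regional_series` data.frame `time, v_wg, v_d, v_f` with
#'   attribute `dispersion` (data.frame region, sd, width95, n_missing).
#' @export
regional_series <- function(traj, regions) {
  if (regions$z0 + regions$z_f > traj$box[3] + 1e-9)
    stop("regions extend above the box top")
  sidx <- solvent_idx(traj)
  nfr <- length(traj$frames)
  vals <- matrix(NA_real_, nfr, 3, dimnames = list(NULL, regions$names))
  for (k in seq_len(nfr)) {
    fr <- traj$frames[[k]]
    rg <- region_of(fr$pos[sidx, 3], regions)
    for (j in seq_along(regions$names)) {
      sel <- which(rg == regions$names[j])
      if (length(sel)) vals[k, j] <- mean(fr$vel[sidx, 1][sel])
    }
  }
  out <- data.frame(time = traj$times, v_wg = vals[, 1], v_d = vals[, 2],
                    v_f = vals[, 3])
  disp <- data.frame(
    region = regions$names,
    sd = apply(vals, 2, stats::sd, na.rm = TRUE),
    width95 = apply(vals, 2, function(x)
      diff(stats::quantile(x, c(0.025, 0.975), na.rm = TRUE, names = FALSE))),
    n_missing = colSums(is.na(vals)))
  attr(out, "dispersion") <- disp
  class(out) <- c("glyco_regional_series", "data.frame")
  out
}

#' Profile roughness (mean absolute second difference)
#'
#' Operationalises the "smoothness" of a binned velocity profile as the
#' mean of |v_{i+2} - 2 v_{i+1} + v_i| over consecutive non-missing bin
#' triples. A linear profile has roughness 0; an alternating +a/-a profile
#' has roughness 4a.
#'
#' @param profile a `glyco_profile` (or any data.frame with `mean_vx`).
#' @return scalar roughness.
#' @export
roughness <- function(profile) {
  v <- profile$mean_vx
  if (sum(!is.na(v)) < 3) stop("need at least 3 non-missing bins")
  d2 <- abs(v[-(1:2)] - 2 * v[-c(1, length(v))] + v[-((length(v) - 1):length(v))])
  d2 <- d2[!is.na(d2)]
  if (length(d2) == 0) stop("no consecutive non-missing bin triple")
  mean(d2)
}

#' Compare the roughness of two slices across time sub-windows
#'
#' Splits the analysis window into `n_windows` disjoint sub-windows,
#' computes the slice roughness in each, and compares the two roughness
#' samples with the two-sample Kolmogorov-Smirnov test from
#' [ks_two_sample()]. With fewer than 5 sub-windows the D statistic is
#' still reported but the asymptotic p-value is NA.
#'
#' @inheritParams slice_profile
#' @param x_a,x_b the two slice centrelines.
#' @param n_windows number of disjoint sub-windows (>= 2).
#' @return list with per-slice roughness samples, `D` and `p`.
#' @export
compare_roughness <- function(traj, regions, x_a, x_b, slice_width = 2,
                              n_bins = 25, window = NULL, n_windows = 5) {
  if (n_windows < 2) stop("need at least 2 time sub-windows")
  win <- if (is.null(window)) range(traj$times) else window
  br <- seq(win[1], win[2], length.out = n_windows + 1)
  rough <- function(xc) vapply(seq_len(n_windows), function(w) {
    roughness(slice_profile(traj, regions, xc, slice_width, n_bins,
                            window = c(br[w], br[w + 1])))
  }, numeric(1))
  ra <- rough(x_a); rb <- rough(x_b)
  if (n_windows >= 5) {
    ks <- ks_two_sample(ra, rb)
    D <- ks$statistic; p <- ks$p.value
  } else {
    D <- ks_statistic(ra, rb); p <- NA_real_
    warning("fewer than 5 sub-windows: reporting D without an asymptotic p-value")
  }
  list(roughness_a = ra, roughness_b = rb, D = D, p = p,
       slices = c(x_a, x_b), windows = cbind(from = br[-length(br)], to = br[-1]))
}
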