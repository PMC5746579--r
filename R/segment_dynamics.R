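#' Align frames on a reference centre of mass
#'
#' Translates every frame so that the mass-weighted centre of mass of the
#' reference selection (the transmembrane/core stand-in) sits at the
#' origin. No rotation is applied: the polar angle theta must stay
#' referenced to the fixed +x flow direction. Velocities are untouched.
#'
#' @param traj a `glyco_trajectory`.
#' @param reference integer particle indices of the reference selection.
#' @return the aligned trajectory (positions are no longer wrapped).
#' @export
align_frames <- function(traj, reference) {
  if (length(reference) == 0) stop("reference selection is empty")
  m <- traj$topology$mass[reference]
  for (k in seq_along(traj$frames)) {
    p <- traj$frames[[k]]$pos
    com <- colSums(p[reference, , drop = FALSE] * m) / sum(m)
    traj$frames[[k]]$pos <- sweep(p, 2, com)
  }
  traj
}

#' Define tracked segments
#'
#' Builds the standard five segment specifications on a chain-bearing
#' topology: P1 and P2 are 5-bead windows centred at 40% of the contour of
#' two chains, P3 and P4 are the 5 terminal beads of two chain tails, and
#' `ecto-core` is the core oligomer of the (first) anchored dimer. Unless
#' chain ids are given, the two tracked chains are auto-selected as those
#' with the largest centre-of-mass displacement range over the trajectory.
#'
#' @param traj a `glyco_trajectory` with chains in its topology.
#' @param chains optional integer vector of two chain ids.
#' @return named list of `glyco_segment` objects (label, members).
#' @export
define_segments <- function(traj, chains = NULL) {
  topo <- traj$topology
  cids <- sort(unique(stats::na.omit(topo$chain_id)))
  if (length(cids) < 2) stop("topology has fewer than two chains")
  if (is.null(chains)) {
    disp <- vapply(cids, function(cid) {
      mem <- which(topo$chain_id == cid)
      xs <- vapply(traj$frames, function(fr)
        mean(fr$pos[mem, 1]), numeric(1))
      diff(range(xs))
    }, numeric(1))
    chains <- cids[order(disp, decreasing = TRUE)][1:2]
  }
  seg <- function(label, members) {
    s <- list(label = label, members = members)
    class(s) <- "glyco_segment"
    s
  }
  mid_window <- function(cid) {
    mem <- which(topo$chain_id == cid)
    mem <- mem[order(topo$chain_pos[mem])]
    n <- length(mem)
    c0 <- max(3L, min(n - 2L, round(0.4 * n)))
    mem[(c0 - 2L):(c0 + 2L)]
  }
  tail_window <- function(cid) {
    mem <- which(topo$chain_id == cid)
    mem <- mem[order(topo$chain_pos[mem])]
    mem[(length(mem) - 4L):length(mem)]
  }
  core <- which(topo$role == "core")
  if (length(core) == 0) stop("topology has no core particles")
  # the core oligomer bearing the first tracked chain: the contiguous run
  # of core indices containing that chain's anchor apex
  apex <- topo$anchor[which(topo$chain_id == chains[1])[1]]
  runs <- split(core, cumsum(c(1, diff(core) != 1)))
  first_core <- runs[[which(vapply(runs, function(r) apex %in% r, logical(1)))[1]]]
  list(P1 = seg("P1", mid_window(chains[1])),
       P2 = seg("P2", mid_window(chains[2])),
       P3 = seg("P3", tail_window(chains[1])),
       P4 = seg("P4", tail_window(chains[2])),
       `ecto-core` = seg("ecto-core", first_core))
}

# make a bead index sequence whole across periodic x,y images by walking
# consecutive members with minimum-image displacements
make_whole <- function(p, Lx, Ly) {
  n <- nrow(p)
  if (n < 2) return(p)
  for (i in 2:n) {
    for (d in 1:2) {
      L <- if (d == 1) Lx else Ly
      delta <- p[i, d] - p[i - 1, d]
      p[i, d] <- p[i - 1, d] + (delta - L * round(delta / L))
    }
  }
  p
}

#' Polar-coordinate track of a segment centre of mass
#'
#' Per frame, the mass-weighted COM of the segment (members made whole
#' across periodic images first); R is the XOY-plane distance of the COM
#' from the aligned reference origin, theta the angle from the +x flow
#' direction, unwrapped to a continuous series across frames. The
#' x-deviation series (COM x minus its time mean) is retained for swing
#' analysis. Frames with R below 1e-12 have undefined theta; these are
#' linearly interpolated in the unwrapped series and counted.
#'
#' @param traj an aligned `glyco_trajectory` (see [align_frames()]).
#' @param segment a `glyco_segment`.
#' @param masses optional member masses (defaults to topology masses).
#' @return a `glyco_track` data.frame `time, x, x_dev, R, theta`.
#' @export
polar_track <- function(traj, segment, masses = NULL) {
  mem <- segment$members
  if (is.null(masses)) masses <- traj$topology$mass[mem]
  if (sum(masses) <= 0) stop("segment total mass must be positive")
  Lx <- traj$box[1]; Ly <- traj$box[2]
  nf <- length(traj$frames)
  com <- matrix(NA_real_, nf, 3)
  for (k in seq_len(nf)) {
    p <- make_whole(traj$frames[[k]]$pos[mem, , drop = FALSE], Lx, Ly)
    com[k, ] <- colSums(p * masses) / sum(masses)
  }
  R <- sqrt(com[, 1]^2 + com[, 2]^2)
  theta_raw <- atan2(com[, 2], com[, 1])
  undef <- R < 1e-12
  theta_raw[undef] <- NA
  theta <- unwrap_angle(theta_raw)
  if (any(undef)) theta <- stats::approx(seq_len(nf)[!undef], theta[!undef],
                                         xout = seq_len(nf), rule = 2)$y
  out <- data.frame(time = traj$times, x = com[, 1],
                    x_dev = com[, 1] - mean(com[, 1]), R = R, theta = theta)
  attr(out, "label") <- segment$label
  attr(out, "n_undefined") <- sum(undef)
  class(out) <- c("glyco_track", "data.frame")
  out
}

# nearest-branch continuation of an angle series (NA tolerated)
unwrap_angle <- function(th) {
  out <- th
  last <- NA_real_
  offset <- 0
  for (i in seq_along(th)) {
    if (is.na(th[i])) next
    if (!is.na(last)) {
      d <- th[i] + offset - last
      offset <- offset - 2 * pi * round(d / (2 * pi))
    }
    out[i] <- th[i] + offset
    last <- out[i]
  }
  out
}

#' Signed winding number of a polar track
#'
#' `floor(|theta_end - theta_start| / 2 pi)` with the sign of the net
#' rotation, on the unwrapped angle series; also reports the number of
#' rotation-direction reversals. Errors when more than 10% of frames had
#' undefined theta (R approximately 0).
#'
#' @param track a `glyco_track` (>= 3 frames).
#' @return list `winding`, `reversals`, `net_angle`.
#' @export
swirl_count <- function(track) {
  if (nrow(track) < 3) stop("need at least 3 frames")
  nu <- attr(track, "n_undefined")
  if (!is.null(nu) && nu > 0.1 * nrow(track))
    stop("more than 10% of frames have undefined theta (R ~ 0)")
  th <- track$theta
  net <- th[length(th)] - th[1]
  winding <- sign(net) * floor(abs(net) / (2 * pi))
  d <- diff(th)
  d <- d[d != 0]
  reversals <- if (length(d) > 1) sum(diff(sign(d)) != 0) else 0L
  list(winding = as.integer(winding), reversals = as.integer(reversals),
       net_angle = net)
}

#' Correlation between two segments' swing motions
#'
#' Pearson correlation of the x-deviation series and of the
#' first-differenced series, with moving-block bootstrap 95% intervals
#' (block length one tenth of the series). Uses the current R RNG; set a
#' seed for reproducible intervals.
#'
#' @param track_a,track_b `glyco_track`s sharing time stamps (>= 20 frames).
#' @param n_boot bootstrap replicates.
#' @return list `r_x`, `r_dx`, `ci_x`, `ci_dx`.
#' @export
motion_correlation <- function(track_a, track_b, n_boot = 200) {
  if (nrow(track_a) != nrow(track_b) ||
      !isTRUE(all.equal(track_a$time, track_b$time)))
    stop("tracks must share identical time stamps")
  n <- nrow(track_a)
  if (n < 20) stop("need at least 20 shared frames")
  xa <- track_a$x_dev; xb <- track_b$x_dev
  block_ci <- function(a, b) {
    L <- max(2L, floor(length(a) / 10))
    starts_max <- length(a) - L + 1L
    nblocks <- ceiling(length(a) / L)
    reps <- vapply(seq_len(n_boot), function(r) {
      st <- sample.int(starts_max, nblocks, replace = TRUE)
      idx <- as.vector(vapply(st, function(s) s:(s + L - 1L),
                              integer(L)))[seq_along(a)]
      suppressWarnings(stats::cor(a[idx], b[idx]))
    }, numeric(1))
    stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  list(r_x = stats::cor(xa, xb),
       r_dx = stats::cor(diff(xa), diff(xb)),
       ci_x = block_ci(xa, xb),
       ci_dx = block_ci(diff(xa), diff(xb)))
}

#' Per-frame chain extension series
#'
#' End-to-end distance (first to last bead, chain made whole across
#' periodic images) and mass-weighted radius of gyration per frame, plus a
#' Mann-Kendall monotone-trend statistic on the end-to-end series flagging
#' net uncoiling.
#'
#' @param traj a `glyco_trajectory`.
#' @param chain_id chain identifier in the topology.
#' @return data.frame `time, ree, rg` with attributes `mk_S`, `mk_p`,
#'   `uncoiling` (TRUE when the trend is significantly increasing at 5%).
#' @export
uncoiling_series <- function(traj, chain_id) {
  topo <- traj$topology
  mem <- which(topo$chain_id == chain_id)
  if (length(mem) < 2) stop("chain must have at least 2 beads")
  mem <- mem[order(topo$chain_pos[mem])]
  if (any(diff(sort(topo$chain_pos[mem])) != 1))
    stop("broken chain indexing for chain ", chain_id)
  m <- topo$mass[mem]
  Lx <- traj$box[1]; Ly <- traj$box[2]
  nf <- length(traj$frames)
  ree <- numeric(nf); rg <- numeric(nf)
  for (k in seq_len(nf)) {
    p <- make_whole(traj$frames[[k]]$pos[mem, , drop = FALSE], Lx, Ly)
    ree[k] <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
    com <- colSums(p * m) / sum(m)
    rg[k] <- sqrt(sum(m * rowSums(sweep(p, 2, com)^2)) / sum(m))
  }
  S <- mann_kendall_s(ree)
  n <- nf
  varS <- n * (n - 1) * (2 * n + 5) / 18
  z <- if (S > 0) (S - 1) / sqrt(varS) else if (S < 0) (S + 1) / sqrt(varS) else 0
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(time = traj$times, ree = ree, rg = rg)
  attr(out, "mk_S") <- S
  attr(out, "mk_p") <- p
  attr(out, "uncoiling") <- (S > 0) && (p < 0.05)
  out
}

mann_kendall_s <- function(x) {
  n <- length(x)
  s <- 0L
  for (i in seq_len(n - 1))
    s <- s + sum(sign(x[(i + 1):n] - x[i]))
  s
}
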