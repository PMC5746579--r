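#' Forward-difference shear stress of a velocity profile
#'
#' \eqn{\tau = \mu \, \partial v_x / \partial z} estimated per bin by the
#' forward difference \eqn{\tau_i = \mu (v_{i+1} - v_i) / (z_{i+1} - z_i)}
#' on bin-centre heights, assigned to the lower bin of each pair. The
#' topmost bin carries no stress value; gaps caused by missing bins yield
#' missing stresses.
#'
#' With a linear profile of unit gradient and the TIP3P-water viscosity
#' 0.321 mPa s, every interior bin reports 0.321 mPa (units follow from
#' those of `mu` and of the profile).
#'
#' @param profile a `glyco_profile` (columns `z_mid`, `mean_vx`).
#' @param mu dynamic viscosity.
#' @return data.frame `z_mid, tau` (tau NA in the topmost bin and at gaps).
#' @export
shear_profile <- function(profile, mu) {
  if (mu <= 0) stop("viscosity mu must be > 0")
  v <- profile$mean_vx; z <- profile$z_mid
  if (all(is.na(v))) stop("all bins missing")
  n <- length(v)
  tau <- rep(NA_real_, n)
  if (n >= 2) {
    dv <- v[-1] - v[-n]
    dz <- z[-1] - z[-n]
    tau[-n] <- mu * dv / dz
  }
  if (all(is.na(tau)))
    stop("no two consecutive non-missing bins: cannot form a forward difference")
  data.frame(z_mid = z, tau = tau)
}

#' Per-instant regional shear-stress series
#'
#' At each cadence tick (nearest recorded frame), the instantaneous
#' whole-extent `n_bins`-bin velocity profile is formed, per-bin forward
#' difference stresses are computed, and stresses are averaged (unweighted)
#' over the bins whose centres fall in each of the wg/d/f regions.
#'
#' @param traj a `glyco_trajectory`.
#' @param regions a `glyco_regions`.
#' @param mu dynamic viscosity.
#' @param cadence tick spacing (>= frame spacing); `NULL` uses every frame.
#' @param n_bins bins of the instantaneous profile (default 25).
#' @return a `glyco_shear_series` data.frame `time, tau_wg, tau_d, tau_f`
#'   with attributes `mu` and `cadence`.
#' @export
shear_series <- function(traj, regions, mu, cadence = NULL, n_bins = 25) {
  tt <- traj$times
  if (is.null(cadence)) {
    fidx <- seq_along(tt)
  } else {
    if (length(tt) > 1 && cadence < min(diff(tt)) - 1e-12)
      stop("cadence finer than the frame spacing")
    ticks <- seq(tt[1], tt[length(tt)], by = cadence)
    fidx <- vapply(ticks, function(t) which.min(abs(tt - t)), integer(1))
  }
  z0 <- regions$z0; ztop <- regions$z0 + regions$z_f
  edges <- seq(z0, ztop, length.out = n_bins + 1)
  zmid <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  memb <- region_of(zmid, regions)
  if (any(!regions$names %in% memb))
    stop("region devoid of profile bins: increase n_bins")
  sidx <- solvent_idx(traj)
  out <- matrix(NA_real_, length(fidx), 3)
  for (r in seq_along(fidx)) {
    fr <- traj$frames[[fidx[r]]]
    bi <- zbin_index(fr$pos[sidx, 3], z0, ztop, n_bins)
    ok <- !is.na(bi)
    v <- rep(NA_real_, n_bins)
    if (any(ok)) {
      mm <- tapply(fr$vel[sidx, 1][ok], bi[ok], mean)
      v[as.integer(names(mm))] <- mm
    }
    tau <- rep(NA_real_, n_bins)
    tau[-n_bins] <- mu * (v[-1] - v[-n_bins]) / (zmid[-1] - zmid[-n_bins])
    for (j in seq_along(regions$names))
      out[r, j] <- mean(tau[memb == regions$names[j]], na.rm = TRUE)
  }
  res <- data.frame(time = tt[fidx], tau_wg = out[, 1], tau_d = out[, 2],
                    tau_f = out[, 3])
  attr(res, "mu") <- mu
  attr(res, "cadence") <- cadence
  class(res) <- c("glyco_shear_series", "data.frame")
  res
}

ks_statistic <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(pts, function(t) mean(b <= t), numeric(1))
  max(abs(Fa - Fb))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs (ties handled
#' by evaluating both ECDFs at every observed value); the p-value uses the
#' asymptotic two-sample distribution with effective size
#' `n_a n_b / (n_a + n_b)`.
#'
#' @param a,b numeric samples, each of size >= 5.
#' @return list with `statistic` (D), `p.value`, `n_a`, `n_b`.
#' @export
ks_two_sample <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 5 || length(b) < 5)
    stop("each sample must contain at least 5 finite values")
  D <- ks_statistic(a, b)
  ne <- length(a) * length(b) / (length(a) + length(b))
  if (D == 0) {
    p <- 1
  } else {
    lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
    k <- 1:100
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
    p <- min(max(p, 0), 1)
  }
  list(statistic = D, p.value = p, n_a = length(a), n_b = length(b))
}

#' Ratio-exceedance report for a regional shear series
#'
#' For each threshold, the fraction of instants with
#' `|tau_num| / |tau_den| > threshold` (direction `">"`), or `< threshold`
#' (direction `"<"`). Instants whose denominator magnitude is below
#' `1e-12` times its RMS are excluded and counted.
#'
#' @param series a `glyco_shear_series`.
#' @param numerator,denominator region names among `"wg", "d", "f"`.
#' @param thresholds numeric thresholds (non-empty).
#' @param direction `">"` or `"<"`.
#' @param scenario optional label (e.g. "three-core").
#' @return a `glyco_exceedance` data.frame `threshold, prob` with
#'   attributes `n_used`, `n_excluded`, `scenario`, `direction`.
#' @export
ratio_exceedance <- function(series, numerator = "wg", denominator = "f",
                             thresholds, direction = ">", scenario = "") {
  if (length(thresholds) == 0) stop("thresholds list must be non-empty")
  if (!direction %in% c(">", "<")) stop("direction must be '>' or '<'")
  num <- abs(series[[paste0("tau_", numerator)]])
  den <- abs(series[[paste0("tau_", denominator)]])
  ok <- is.finite(num) & is.finite(den)
  num <- num[ok]; den <- den[ok]
  if (length(den) == 0) stop("series has no usable instants")
  floor_ <- 1e-12 * sqrt(mean(den^2))
  keep <- den > floor_
  if (!any(keep)) stop("all instants excluded by near-zero denominators")
  ratio <- num[keep] / den[keep]
  prob <- vapply(thresholds, function(th)
    if (direction == ">") mean(ratio > th) else mean(ratio < th), numeric(1))
  out <- data.frame(threshold = thresholds, prob = prob)
  attr(out, "n_used") <- sum(keep)
  attr(out, "n_excluded") <- sum(!keep)
  attr(out, "scenario") <- scenario
  attr(out, "direction") <- direction
  class(out) <- c("glyco_exceedance", "data.frame")
  out
}

#' Compare two simulation scenarios' shear statistics
#'
#' Exceedance reports for both scenarios on identical thresholds (both the
#' strong near-wall ratio |tau_wg|/|tau_f| with direction ">" and the weak
#' dendritic ratio |tau_d|/|tau_f| with direction "<"), plus per-region
#' two-sample K-S comparisons of the |tau| distributions.
#'
#' @param series_a,series_b `glyco_shear_series` objects with equal `mu`.
#' @param thresholds thresholds for the ">" report; the "<" report uses
#'   `rev(1 / thresholds)` unless `thresholds_lt` is given.
#' @param thresholds_lt optional thresholds for the "<" report.
#' @param labels scenario labels.
#' @return list with `exceedance` (long data.frame), `ks` (per-region
#'   data.frame D, p).
#' @export
compare_scenarios <- function(series_a, series_b,
                              thresholds = c(1, 1.5, 2, 2.5, 3),
                              thresholds_lt = c(0.75, 0.5, 0.25, 0.1),
                              labels = c("A", "B")) {
  if (!isTRUE(all.equal(attr(series_a, "mu"), attr(series_b, "mu"))))
    stop("scenarios use different viscosities mu")
  rows <- list()
  for (s in 1:2) {
    ser <- list(series_a, series_b)[[s]]
    gt <- ratio_exceedance(ser, "wg", "f", thresholds, ">", labels[s])
    lt <- ratio_exceedance(ser, "d", "f", thresholds_lt, "<", labels[s])
    rows[[length(rows) + 1]] <- data.frame(scenario = labels[s],
                                           ratio = "|tau_wg|/|tau_f|",
                                           direction = ">", gt)
    rows[[length(rows) + 1]] <- data.frame(scenario = labels[s],
                                           ratio = "|tau_d|/|tau_f|",
                                           direction = "<", lt)
  }
  ks <- do.call(rbind, lapply(c("wg", "d", "f"), function(rg) {
    a <- abs(series_a[[paste0("tau_", rg)]])
    b <- abs(series_b[[paste0("tau_", rg)]])
    k <- ks_two_sample(a[is.finite(a)], b[is.finite(b)])
    data.frame(region = rg, D = k$statistic, p = k$p.value)
  }))
  list(exceedance = do.call(rbind, rows), ks = ks)
}

#' Reynolds number and laminarity classification
#'
#' `Re = rho v L / mu`; `Re < 1` is classified "creeping/laminar",
#' `Re < 2000` "laminar", otherwise "transitional/turbulent". With the
#' physiological upper-range parameters (rho = 1000 kg/m3, v = 1 mm/s,
#' L = 50 nm, mu = 0.321 mPa s) Re is about 1.6e-4.
#'
#' @param rho fluid density.
#' @param v characteristic velocity.
#' @param L characteristic length.
#' @param mu dynamic viscosity.
#' @return list `Re`, `regime`.
#' @export
reynolds_number <- function(rho, v, L, mu) {
  vals <- c(rho = rho, v = v, L = L, mu = mu)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all inputs to reynolds_number must be strictly positive")
  Re <- rho * v * L / mu
  regime <- if (Re < 1) "creeping/laminar" else if (Re < 2000) "laminar"
  else "transitional/turbulent"
  list(Re = Re, regime = regime)
}

#' Estimate the reduced viscosity from a chain-free channel profile
#'
#' Fits a parabola to the interior of a time-averaged v_x(z) profile of a
#' body-forced channel (Poiseuille flow: \eqn{v'' = -\rho f_x / \mu}) and
#' returns \eqn{\mu = -\rho f_x / (2 a)} where `a` is the fitted quadratic
#' coefficient. Intended for a one-off calibration run without chains.
#'
#' @param profile a `glyco_profile` from a control (chain-free) run.
#' @param rho solvent number density (beads per sigma^3).
#' @param f_x body force per bead used in the run.
#' @param trim number of bins dropped at each wall.
#' @return estimated dynamic viscosity (reduced units).
#' @export
estimate_viscosity <- function(profile, rho, f_x, trim = 3) {
  ok <- which(!is.na(profile$mean_vx))
  ok <- ok[ok > trim & ok <= nrow(profile) - trim]
  if (length(ok) < 5) stop("too few interior bins for a parabolic fit")
  z <- profile$z_mid[ok]; v <- profile$mean_vx[ok]
  fit <- stats::lm(v ~ z + I(z^2))
  a <- stats::coef(fit)[["I(z^2)"]]
  if (a >= 0) stop("profile is not concave: cannot estimate viscosity")
  -rho * f_x / (2 * a)
}
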