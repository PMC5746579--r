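test_that("shear_profile worked example, closed forms and oracle", {
  # unit velocity gradient with the TIP3P viscosity: tau = 0.321 everywhere
  prof <- data.frame(z_mid = seq(0.5, 24.5, by = 1), mean_vx = seq(0.5, 24.5, by = 1))
  tau <- shear_profile(prof, mu = 0.321)
  expect_equal(tau$tau[-nrow(tau)], rep(0.321, 24))
  expect_true(is.na(tau$tau[nrow(tau)]))  # topmost bin has no stress

  uni <- data.frame(z_mid = 1:10, mean_vx = rep(2, 10))
  expect_true(all(shear_profile(uni, 1)$tau[-10] == 0))

  # 5-bin hand profile against brute-force pairwise differences
  hp <- data.frame(z_mid = c(1, 2, 3, 4, 5), mean_vx = c(0, 1, -1, 4, 2))
  th <- shear_profile(hp, mu = 2)
  expect_equal(th$tau, c(2 * diff(hp$mean_vx) / diff(hp$z_mid), NA))

  # missing-bin gaps propagate
  gp <- data.frame(z_mid = 1:4, mean_vx = c(1, NA, 3, 4))
  tg <- shear_profile(gp, 1)
  expect_true(is.na(tg$tau[1]) && is.na(tg$tau[2]))
  expect_equal(tg$tau[3], 1)

  expect_error(shear_profile(data.frame(z_mid = 1:3,
                                        mean_vx = rep(NA_real_, 3)), 1),
               "missing")
  expect_error(shear_profile(prof, mu = 0), "mu")
})

test_that("shear_profile is linear in the profile and in mu", {
  set.seed(6)
  prof <- data.frame(z_mid = 1:12, mean_vx = stats::rnorm(12))
  t1 <- shear_profile(prof, 0.5)$tau
  prof3 <- prof; prof3$mean_vx <- 3 * prof$mean_vx
  expect_equal(shear_profile(prof3, 0.5)$tau, 3 * t1)
  expect_equal(shear_profile(prof, 1.5)$tau, 3 * t1)
  # sign follows the local forward difference
  expect_equal(sign(t1[-12]), sign(diff(prof$mean_vx)))
})

test_that("shear_series recovers steady fields and hand enumeration", {
  box <- c(8, 8, 16)
  reg <- partition_regions(0, c(4, 10, 16))
  slope <- 0.3
  fr <- grid_frame(box, nz = 64, vf = function(x, y, z) c(slope * z, 0, 0))
  tr <- make_traj(list(fr, fr), times = c(0, 1), box = box)
  ss <- shear_series(tr, reg, mu = 2, n_bins = 8)
  expect_equal(unlist(ss[, 2:4]), rep(2 * slope, 6), ignore_attr = TRUE,
               tolerance = 1e-9)

  # piecewise-linear, steeper in wg: |tau_wg| > |tau_f| at every instant
  vf <- function(x, y, z) c(ifelse(z < 4, z, 4 + 0.2 * (z - 4)), 0, 0)
  fr2 <- grid_frame(box, nz = 64, vf = vf)
  tr2 <- make_traj(list(fr2, fr2, fr2), times = 0:2, box = box)
  s2 <- shear_series(tr2, reg, mu = 1, n_bins = 8)
  expect_true(all(abs(s2$tau_wg) > abs(s2$tau_f)))

  # 2-tick enumeration oracle with 4 bins: bin width 4, centres 2,6,10,14
  mk <- function(vs) list(pos = cbind(1, 1, c(2, 6, 10, 14)),
                          vel = cbind(vs, 0, 0))
  trh <- make_traj(list(mk(c(0, 2, 3, 1)), mk(c(1, 1, 5, 2))),
                   times = c(0, 1), box = box)
  sh <- shear_series(trh, reg, mu = 1, n_bins = 4)
  # region membership of bin centres: wg = {2}, d = {6}, f = {10, 14};
  # forward differences: tau_i = (v[i+1]-v[i])/4 at bins 1..3
  expect_equal(sh$tau_wg, c((2 - 0) / 4, (1 - 1) / 4))
  expect_equal(sh$tau_d, c((3 - 2) / 4, (5 - 1) / 4))
  expect_equal(sh$tau_f, c((1 - 3) / 4, (2 - 5) / 4))
  expect_error(shear_series(trh, reg, mu = 1, n_bins = 2), "devoid")
})

test_that("ks_two_sample closed cases and exhaustive enumeration oracle", {
  x <- c(1, 2, 3, 4, 5)
  k1 <- ks_two_sample(x, x)
  expect_equal(k1$statistic, 0)
  expect_equal(k1$p.value, 1)

  ksep <- ks_two_sample(1:6, 11:16)
  expect_equal(ksep$statistic, 1)
  expect_lt(ksep$p.value, 0.05)

  # small closed-form case: D({1,2,3},{2,3,4}) = 1/3 by direct ECDF
  # evaluation at all six points (the public API enforces n >= 5)
  expect_equal(glycoflow:::ks_statistic(c(1, 2, 3), c(2, 3, 4)), 1 / 3)

  expect_error(ks_two_sample(1:3, 1:10), "5")

  # full enumeration: every multiset of sizes 5 and 6 over {0,1,2,3},
  # D compared against the independent stats::ks.test implementation
  msets <- function(k) {
    g <- expand.grid(rep(list(0:3), k))
    unique(t(apply(g, 1, sort)))
  }
  all5 <- msets(5); all6 <- msets(6)
  pool <- rbind(cbind(all5, NA), all6)
  set.seed(1)
  take <- pool[sample(nrow(pool), 40), , drop = FALSE]
  for (i in seq_len(nrow(take))) for (j in seq_len(nrow(take))) {
    a <- take[i, ]; a <- a[!is.na(a)]
    b <- take[j, ]; b <- b[!is.na(b)]
    D <- ks_two_sample(a, b)$statistic
    Dref <- suppressWarnings(unname(stats::ks.test(a, b)$statistic))
    if (abs(D - Dref) > 1e-12)
      fail(sprintf("D mismatch for {%s} vs {%s}", paste(a, collapse = ","),
                   paste(b, collapse = ",")))
  }
  succeed()
})

test_that("ratio_exceedance counts, excludes and stays monotone", {
  ser <- data.frame(time = 1:5, tau_wg = rep(2, 5), tau_d = rep(0.5, 5),
                    tau_f = rep(1, 5))
  class(ser) <- c("glyco_shear_series", "data.frame")
  attr(ser, "mu") <- 1
  r <- ratio_exceedance(ser, "wg", "f", c(1.5, 2.5))
  expect_equal(r$prob, c(1, 0))

  # 10-instant hand series: exhaustive counting oracle
  set.seed(3)
  s10 <- data.frame(time = 1:10, tau_wg = stats::rnorm(10),
                    tau_d = stats::rnorm(10), tau_f = stats::rnorm(10))
  class(s10) <- c("glyco_shear_series", "data.frame")
  th <- c(0.5, 1, 2)
  r10 <- ratio_exceedance(s10, "wg", "f", th)
  manual <- vapply(th, function(t)
    sum(abs(s10$tau_wg) / abs(s10$tau_f) > t) / 10, numeric(1))
  expect_equal(r10$prob, manual)
  expect_true(all(diff(r10$prob) <= 0))  # non-increasing for ">"

  rlt <- ratio_exceedance(s10, "d", "f", sort(th), "<")
  expect_true(all(diff(rlt$prob) >= 0))  # non-decreasing for "<"

  expect_error(ratio_exceedance(s10, "wg", "f", numeric(0)), "non-empty")

  # near-zero denominators are excluded and reported
  sz <- s10; sz$tau_f[3] <- 0
  rz <- ratio_exceedance(sz, "wg", "f", 1)
  expect_equal(attr(rz, "n_excluded"), 1L)
  expect_equal(attr(rz, "n_used"), 9L)
})

test_that("compare_scenarios identity, dominance and mu guard", {
  set.seed(9)
  mk <- function(scale_wg = 1) {
    s <- data.frame(time = 1:40, tau_wg = scale_wg * stats::rnorm(40),
                    tau_d = stats::rnorm(40), tau_f = stats::rnorm(40))
    class(s) <- c("glyco_shear_series", "data.frame")
    attr(s, "mu") <- 0.321
    s
  }
  a <- mk()
  cmpAA <- compare_scenarios(a, a, labels = c("one", "two"))
  expect_true(all(cmpAA$ks$D == 0))
  pa <- cmpAA$exceedance[cmpAA$exceedance$scenario == "one", "prob"]
  pb <- cmpAA$exceedance[cmpAA$exceedance$scenario == "two", "prob"]
  expect_equal(pa, pb)

  b <- a; b$tau_wg <- 2 * a$tau_wg
  attr(b, "mu") <- 0.321
  cmpAB <- compare_scenarios(a, b, labels = c("A", "B"))
  ex <- cmpAB$exceedance
  gtA <- ex[ex$scenario == "A" & ex$direction == ">", "prob"]
  gtB <- ex[ex$scenario == "B" & ex$direction == ">", "prob"]
  expect_true(all(gtB >= gtA))

  bad <- a; attr(bad, "mu") <- 1
  expect_error(compare_scenarios(a, bad), "mu")
})

test_that("reynolds_number arithmetic, classification and guards", {
  expect_equal(reynolds_number(1, 1, 1, 1)$Re, 1)
  phys <- reynolds_number(rho = 1000, v = 1e-3, L = 50e-9, mu = 0.321e-3)
  expect_equal(phys$Re, 1000 * 1e-3 * 50e-9 / 0.321e-3, tolerance = 1e-12)
  expect_equal(phys$regime, "creeping/laminar")
  expect_equal(reynolds_number(1000, 2e-3, 50e-9, 0.321e-3)$Re,
               2 * phys$Re, tolerance = 1e-12)
  expect_error(reynolds_number(-1, 1, 1, 1), "positive")
})

test_that("viscosity calibration recovers a known parabola", {
  # synthetic Poiseuille profile: v = (rho f / 2 mu) z (H - z)
  rho <- 0.4; f <- 0.05; mu <- 2; H <- 20
  z <- seq(0.4, H - 0.4, by = 0.8)
  prof <- data.frame(z_mid = z, mean_vx = rho * f / (2 * mu) * z * (H - z))
  class(prof) <- c("glyco_profile", "data.frame")
  expect_equal(estimate_viscosity(prof, rho, f), mu, tolerance = 1e-6)
})
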