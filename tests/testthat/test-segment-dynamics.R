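seg <- function(members, label = "S") {
  s <- list(label = label, members = members)
  class(s) <- "glyco_segment"
  s
}

test_that("align_frames translates the reference COM to the origin", {
  pos <- rbind(c(3, 4, 5), c(4, 4, 5), c(8, 1, 2))
  vel <- matrix(0, 3, 3)
  tr <- make_traj(list(list(pos = pos, vel = vel),
                       list(pos = pos + 1, vel = vel)),
                  times = c(0, 1), box = c(20, 20, 20))
  al <- align_frames(tr, reference = 1:2)
  for (k in 1:2)
    expect_equal(colMeans(al$frames[[k]]$pos[1:2, ]), c(0, 0, 0))
  # already-aligned frame stays put
  al2 <- align_frames(al, reference = 1:2)
  expect_equal(al2$frames[[1]]$pos, al$frames[[1]]$pos)
  expect_error(align_frames(tr, integer(0)), "empty")
})

test_that("polar_track closed positions and mass-weighted enumeration", {
  mk <- function(p) list(pos = matrix(p, ncol = 3, byrow = TRUE),
                         vel = matrix(0, length(p) / 3, 3))
  tr <- make_traj(list(mk(c(1, 0, 2)), mk(c(0, 2, 2))), times = c(0, 1),
                  box = c(40, 40, 10))
  t1 <- polar_track(tr, seg(1))
  expect_equal(t1$R, c(1, 2))
  expect_equal(t1$theta[1], 0)
  expect_equal(t1$theta[2], pi / 2)

  # 3-frame, 2-bead case with masses 1 and 2: brute-force COM arithmetic
  frames <- list(mk(c(0, 0, 0, 3, 0, 0)), mk(c(0, 3, 0, 0, 0, 0)),
                 mk(c(-1, 0, 0, -4, 0, 0)))
  tr2 <- make_traj(frames, times = 0:2, box = c(40, 40, 10))
  tr2$topology$mass <- c(1, 2)
  t2 <- polar_track(tr2, seg(1:2))
  com_x <- c((0 + 2 * 3) / 3, 0, (-1 - 8) / 3)
  com_y <- c(0, 3 / 3, 0)
  expect_equal(t2$R, sqrt(com_x^2 + com_y^2))
  expect_equal(t2$x_dev, com_x - mean(com_x))
  expect_error(polar_track(tr2, seg(1:2), masses = c(0, 0)), "mass")
})

test_that("R and theta ignore rigid pre-alignment translations", {
  set.seed(12)
  pos <- cbind(stats::runif(6, 8, 12), stats::runif(6, 8, 12),
               stats::runif(6, 2, 8))
  tr <- make_traj(list(list(pos = pos, vel = matrix(0, 6, 3))),
                  box = c(40, 40, 10))
  shift <- c(2.5, -1.5, 3)
  trs <- tr
  trs$frames[[1]]$pos <- sweep(pos, 2, shift, `+`)
  a <- polar_track(align_frames(tr, 1:2), seg(3:4))
  b <- polar_track(align_frames(trs, 1:2), seg(3:4))
  expect_equal(a$R, b$R, tolerance = 1e-12)
  expect_equal(a$theta, b$theta, tolerance = 1e-12)
})

test_that("swirl_count winding numbers and sign convention", {
  circle <- function(angles, r = 2)
    lapply(angles, function(a) list(pos = matrix(c(r * cos(a), r * sin(a), 1),
                                                 1), vel = matrix(0, 1, 3)))
  # one full counter-clockwise revolution
  ang <- seq(0, 2 * pi, length.out = 40)
  tr <- make_traj(circle(ang), times = seq_along(ang), box = c(40, 40, 10))
  t1 <- polar_track(tr, seg(1))
  expect_equal(swirl_count(t1)$winding, 1L)

  # static segment
  trs <- make_traj(circle(rep(0.3, 10)), times = 1:10, box = c(40, 40, 10))
  expect_equal(swirl_count(polar_track(trs, seg(1)))$winding, 0L)

  # 720 degrees clockwise: winding -2
  ang2 <- seq(0, -4 * pi, length.out = 101)
  tr2 <- make_traj(circle(ang2), times = seq_along(ang2), box = c(40, 40, 10))
  t2 <- polar_track(tr2, seg(1))
  expect_equal(swirl_count(t2)$winding, -2L)

  # winding survives dropping every other frame (angular steps < pi)
  half <- make_traj(circle(ang2[seq(1, 101, by = 2)]), times = 1:51,
                    box = c(40, 40, 10))
  expect_equal(swirl_count(polar_track(half, seg(1)))$winding, -2L)

  expect_error(swirl_count(t1[1:2, ]), "3")
})

test_that("motion_correlation recovers self, negation and independence", {
  set.seed(21)
  n <- 1000
  mk_track <- function(x) {
    d <- data.frame(time = seq_len(length(x)), x = x, x_dev = x - mean(x),
                    R = abs(x) + 1, theta = 0)
    class(d) <- c("glyco_track", "data.frame")
    d
  }
  x <- cumsum(stats::rnorm(n))
  a <- mk_track(x)
  self <- motion_correlation(a, a, n_boot = 20)
  expect_equal(self$r_x, 1)
  neg <- motion_correlation(a, mk_track(-x), n_boot = 20)
  expect_equal(neg$r_x, -1)
  expect_error(motion_correlation(a[1:10, ], a[1:10, ]), "20")
  expect_error(motion_correlation(a, mk_track(x[c(2:n, 1)])[c(2:n, 1), ]),
               "time")

  # two independent white-noise tracks: |r| < 0.1 in >= 95% of replicates
  hits <- 0L
  for (r in 1:100) {
    set.seed(1000 + r)
    ra <- mk_track(stats::rnorm(n))
    rb <- mk_track(stats::rnorm(n))
    cc <- stats::cor(ra$x_dev, rb$x_dev)
    if (abs(cc) < 0.1) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

chain_traj <- function(frames_pos, box = c(20, 20, 20)) {
  n <- nrow(frames_pos[[1]])
  tr <- make_traj(lapply(frames_pos, function(p)
    list(pos = p, vel = matrix(0, n, 3))),
    times = seq_along(frames_pos), box = box)
  tr$topology$role <- rep("chain", n)
  tr$topology$chain_id <- rep(1L, n)
  tr$topology$chain_pos <- seq_len(n)
  tr
}

test_that("uncoiling_series end-to-end, gyration and periodic wholeness", {
  b <- 0.9
  straight <- cbind(5 + b * (0:5), 5, 5)
  tr <- chain_traj(list(straight))
  u <- uncoiling_series(tr, 1)
  expect_equal(u$ree, 5 * b)

  # chain folded exactly in half (even bead count): end-to-end ~ 0
  folded <- rbind(cbind(5 + b * (0:2), 5, 5), cbind(5 + b * (2:0), 5 + 1e-9, 5))
  uf <- uncoiling_series(chain_traj(list(folded)), 1)
  expect_lt(uf$ree, 1e-6)

  # 4-bead hand conformation: brute-force radius of gyration
  p4 <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 2)) + 5
  u4 <- uncoiling_series(chain_traj(list(p4)), 1)
  com <- colMeans(p4)
  rg_bf <- sqrt(mean(rowSums(sweep(p4, 2, com)^2)))
  expect_equal(u4$rg, rg_bf)

  # a chain written across the periodic x boundary is made whole
  split <- cbind(c(19.6, 0.5, 1.4), 5, 5)
  us <- uncoiling_series(chain_traj(list(split)), 1)
  expect_equal(us$ree, 1.8, tolerance = 1e-9)

  # end-to-end never exceeds contour length on random walks
  set.seed(33)
  for (r in 1:5) {
    steps <- matrix(stats::rnorm(30, sd = 0.4), 10, 3)
    p <- apply(steps, 2, cumsum) + 10
    ur <- uncoiling_series(chain_traj(list(p)), 1)
    contour <- sum(sqrt(rowSums(diff(p)^2)))
    expect_lte(ur$ree, contour + 1e-9)
  }

  # monotone trend statistic flags a steadily extending chain
  grow <- lapply(seq(0.3, 0.9, length.out = 25), function(bb)
    cbind(5 + bb * (0:5), 5, 5))
  ug <- uncoiling_series(chain_traj(grow), 1)
  expect_gt(attr(ug, "mk_S"), 0)
  expect_true(attr(ug, "uncoiling"))

  bad <- chain_traj(list(straight))
  bad$topology$chain_pos <- c(1, 3, 4, 5, 6, 7)
  expect_error(uncoiling_series(bad, 1), "broken")
})

test_that("define_segments picks 40% windows, tails and the bearing core", {
  cfg <- sim_config(Lx = 14, Ly = 14, Lz = 24, n_solvent = 300, n_cores = 1,
                    chains_per_core = 6, beads_per_chain = 10, core_beads = 4,
                    f_x = 0.05, n_steps = 300, record_interval = 30,
                    n_equil = 200, seed = 8)
  traj <- run_simulation(cfg)
  al <- align_frames(traj, which(traj$topology$role == "core"))
  segs <- define_segments(al)
  expect_named(segs, c("P1", "P2", "P3", "P4", "ecto-core"))
  topo <- traj$topology
  for (nm in c("P1", "P2", "P3", "P4"))
    expect_length(segs[[nm]]$members, 5)
  # P1 window centred at 40% of a 10-bead chain (position 4)
  expect_equal(topo$chain_pos[segs$P1$members], 2:6)
  expect_equal(topo$chain_pos[segs$P3$members], 6:10)
  expect_true(all(topo$role[segs$`ecto-core`$members] == "core"))
})
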