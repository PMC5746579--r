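test_that("build_system constructs the stated particle inventory", {
  cfg0 <- tiny_config(n_cores = 0L)
  st0 <- build_system(cfg0)
  expect_equal(sum(st0$role == "chain"), 0)
  expect_equal(sum(st0$role == "core"), 0)
  n_frozen <- sum(st0$role %in% c("wall", "ceiling"))
  expect_equal(nrow(st0$pos), cfg0$n_solvent + n_frozen)

  cfg3 <- sim_config(Lx = 14, Ly = 14, Lz = 24, n_solvent = 400, n_cores = 3,
                     chains_per_core = 6, beads_per_chain = 5, core_beads = 4,
                     n_steps = 0, record_interval = 1)
  st3 <- build_system(cfg3)
  expect_equal(sum(st3$role == "chain"), 3 * 6 * 5)
  # every chain bead belongs to exactly one chain, contiguous indexing
  ch <- st3$chain_id[st3$role == "chain"]
  expect_false(anyNA(ch))
  expect_equal(unname(table(ch)), rep(5L, 18), ignore_attr = TRUE)
  # immobile particles have zero velocity; mobile are thermal
  expect_true(all(st3$vel[!st3$mobile, ] == 0))
  expect_gt(stats::sd(st3$vel[st3$mobile, 1]), 0.5)
  # packing contract: minimum solvent pair distance >= 0.8 r_c
  sol <- st3$pos[st3$role == "solvent", ]
  sub <- sol[seq_len(200), ]
  dmin <- min(stats::dist(sub))
  expect_gte(dmin, 0.8 * cfg3$r_c - 1e-9)
})

test_that("build_system is deterministic and errors on impossible packing", {
  cfg <- tiny_config(seed = 11L)
  expect_identical(build_system(cfg), build_system(cfg))
  expect_error(sim_config(Lx = 5, Ly = 5, Lz = 6, n_solvent = 500),
               "too large")
  cfg_dense <- tiny_config()
  cfg_dense$n_solvent <- 1100L  # below the crude validator, above RSA jamming
  expect_error(build_system(cfg_dense), "density")
})

test_that("config invariants are enforced", {
  expect_error(tiny_config(n_cores = 2L), "n_cores")
  expect_error(sim_config(dt = -0.1), "positive")
  expect_error(sim_config(n_steps = 100, record_interval = 33), "divide")
  expect_error(sim_config(gamma = 300, dt = 0.005), "probability")
})

test_that("compute_forces honours cut-off, body force and bond minimum", {
  cfg <- tiny_config()
  # two unbonded non-solvent beads beyond r_c: zero mutual force
  st <- free_state(rbind(c(5, 5, 5), c(5 + cfg$r_c + 0.1, 5, 5)),
                   box = c(20, 20, 20), role = "core")
  f <- compute_forces(st, cfg)
  expect_equal(f, matrix(0, 2, 3))
  # a single solvent bead: exactly the body force
  st1 <- free_state(c(5, 5, 5), box = c(20, 20, 20))
  expect_equal(compute_forces(st1, cfg)[1, ], c(cfg$f_x, 0, 0))
  # bonded pair at rest length (beyond the WCA cut-off): zero force on the
  # bond axis
  st2 <- free_state(rbind(c(5, 5, 5), c(6.3, 5, 5)), box = c(20, 20, 20),
                    role = "core")
  st2 <- add_bond(st2, 1, 2, r0 = 1.3, k = 100)
  expect_equal(compute_forces(st2, cfg), matrix(0, 2, 3), tolerance = 1e-12)
  # overlap below the hard floor is an integration blow-up signal
  st3 <- free_state(rbind(c(5, 5, 5), c(5.1, 5, 5)), box = c(20, 20, 20))
  expect_error(compute_forces(st3, cfg), "hard floor")
})

test_that("velocity Verlet matches one-step closed form and leaves rest state", {
  cfg <- tiny_config(f_x = 0.3)
  cfg$gamma <- 0
  v0 <- c(0.1, -0.2, 0.05)
  st <- free_state(c(5, 5, 5), vel = v0, box = c(20, 20, 20))
  st1 <- step_velocity_verlet(st, cfg)
  f <- c(cfg$f_x, 0, 0)
  expect_equal(st1$pos[1, ], c(5, 5, 5) + v0 * cfg$dt + f * cfg$dt^2 / 2,
               tolerance = 1e-12)
  expect_equal(st1$time, cfg$dt)
  # zero force, zero velocity: unchanged except time
  cfg0 <- tiny_config(f_x = 0)
  str <- free_state(c(5, 5, 5), box = c(20, 20, 20), role = "core")
  str1 <- step_velocity_verlet(str, cfg0)
  expect_equal(str1$pos, str$pos)
  expect_equal(str1$vel, str$vel)
  expect_equal(str1$time, cfg0$dt)
})

test_that("velocity Verlet tracks the harmonic oscillator closed form", {
  # oscillator via a unit-stiffness tether: omega = 1, period 2*pi
  period <- 2 * pi
  dt <- period / 100
  cfg <- tiny_config(f_x = 0)
  cfg$dt <- dt
  cfg$gamma <- 0
  st <- free_state(c(26, 25, 25), box = c(50, 50, 50), role = "core")
  st <- add_tether(st, 1, c(25, 25, 25), k = 1)
  out <- glycoflow:::run_steps(st, cfg, n_steps = 10000L, record_every = 100L,
                               thermostat = FALSE)
  x <- vapply(out$positions, function(p) p[1, 1] - 25, numeric(1))
  v <- vapply(out$velocities, function(p) p[1, 1], numeric(1))
  tt <- out$times
  expect_lt(max(abs(x - cos(tt))), 1e-2)        # amplitude-scale error
  energy <- 0.5 * v^2 + 0.5 * x^2
  expect_lt(max(abs(energy - energy[1])) / energy[1], 1e-3)
})

test_that("Lowe-Andersen sweep conserves pair momentum and respects gamma", {
  cfg <- tiny_config()
  st <- free_state(rbind(c(5, 5, 5), c(5.9, 5, 5)),
                   vel = rbind(c(0.4, 0.1, 0), c(-0.3, 0.2, 0.1)),
                   box = c(20, 20, 20))
  # gamma = 0 leaves the state unchanged
  cfg0 <- cfg; cfg0$gamma <- 0
  expect_identical(lowe_andersen_collide(st, cfg0), st)
  # force a collision (probability gamma*dt close to 1) and check momentum
  cfgc <- cfg; cfgc$gamma <- 190; cfgc$dt <- 0.005
  hit <- FALSE
  for (s in 1:20) {
    st1 <- lowe_andersen_collide(st, cfgc, seed = s)
    expect_equal(colSums(st1$vel), colSums(st$vel), tolerance = 1e-12)
    if (!isTRUE(all.equal(st1$vel, st$vel))) hit <- TRUE
  }
  expect_true(hit)
  cfgbad <- cfg; cfgbad$gamma <- 1000
  expect_error(lowe_andersen_collide(st, cfgbad), "probability")
})

test_that("thermostat is Galilean invariant", {
  # boosting all velocities by a uniform amount commutes with the sweep
  cfg <- tiny_config(); cfg$gamma <- 150
  set.seed(4)
  pos <- cbind(stats::runif(20, 4, 6), stats::runif(20, 4, 6),
               stats::runif(20, 4, 6))
  pos <- pos + seq_len(20) * 1e-3  # avoid exact overlaps
  vel <- matrix(stats::rnorm(60), 20, 3)
  st <- free_state(pos, vel, box = c(20, 20, 20))
  boost <- c(3, -1, 0.5)
  stb <- st; stb$vel <- sweep(st$vel, 2, boost, `+`)
  out <- lowe_andersen_collide(st, cfg, seed = 99)
  outb <- lowe_andersen_collide(stb, cfg, seed = 99)
  expect_equal(sweep(outb$vel, 2, boost), out$vel, tolerance = 1e-10)
})

test_that("equilibrium run thermostats to the target temperature", {
  cfg <- sim_config(Lx = 9, Ly = 9, Lz = 14, n_solvent = 350, n_cores = 0,
                    f_x = 0, n_steps = 4000, record_interval = 100,
                    n_equil = 1000, seed = 5)
  traj <- run_simulation(cfg)
  Tbar <- mean(traj$log$kinetic_T[-(1:10)])
  expect_lt(abs(Tbar - cfg$temperature) / cfg$temperature, 0.02)
})

test_that("momentum is conserved without walls (thermostat on, f_x = 0)", {
  cfg <- tiny_config(f_x = 0)
  set.seed(7)
  g <- as.matrix(expand.grid(x = seq(2, 8, by = 1.5), y = seq(2, 8, by = 1.5),
                             z = seq(4, 10, by = 1.5)))
  vel <- matrix(stats::rnorm(3 * nrow(g)), ncol = 3)
  st <- free_state(g, vel, box = c(10, 10, 60))
  out <- glycoflow:::run_steps(st, cfg, n_steps = 2000L, record_every = 500L,
                               thermostat = TRUE, seed = 13)
  p0 <- colSums(out$velocities[[1]])
  pT <- colSums(out$velocities[[length(out$velocities)]])
  expect_equal(pT, p0, tolerance = 1e-9)
})

test_that("runs are deterministic, tethered, and respond to forcing", {
  cfg <- tiny_config(seed = 21L)
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$times, t2$times)

  # n_steps = 0 keeps exactly the initial frame
  cfg0 <- tiny_config(n_steps = 0L)
  tr0 <- run_simulation(cfg0)
  expect_length(tr0$frames, 1L)

  # tethering: first chain bead stays within 2 rest lengths of its anchor
  topo <- t1$topology
  first_beads <- which(topo$role == "chain" & topo$chain_pos == 1)
  for (b in first_beads) {
    a <- topo$anchor[b]
    d <- vapply(t1$frames, function(fr) {
      dd <- fr$pos[b, ] - fr$pos[a, ]
      dd[1:2] <- dd[1:2] - t1$box[1:2] * round(dd[1:2] / t1$box[1:2])
      sqrt(sum(dd^2))
    }, numeric(1))
    expect_lt(max(d), 2)
  }

  # forced-flow monotonicity over a 2-point force ladder, same seed
  lo <- run_simulation(tiny_config(seed = 31L, f_x = 0.01, n_steps = 1500L,
                                   record_interval = 50L))
  hi <- run_simulation(tiny_config(seed = 31L, f_x = 0.06, n_steps = 1500L,
                                   record_interval = 50L))
  m_lo <- mean(lo$log$mean_vx[-(1:10)])
  m_hi <- mean(hi$log$mean_vx[-(1:10)])
  expect_gt(m_lo, 0)
  expect_gt(m_hi, m_lo)
})
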