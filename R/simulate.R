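#' Per-particle forces
#'
#' Sum of (i) purely repulsive short-range (WCA) pair forces truncated at
#' min(r_c, 2^(1/6)), (ii) harmonic bond forces along chains and cores and
#' at tethers, (iii) a cosine angle-stiffening term along core oligomers
#' only, and (iv) the constant body force `f_x` on solvent beads above the
#' wall surface. Forces on immobile particles are computed (and returned)
#' but never applied by the integrator.
#'
#' @param state a `glyco_state`.
#' @param cfg the matching [sim_config()].
#' @return an n x 3 matrix of forces (reduced units).
#' @export
compute_forces <- function(state, cfg) {
  stopifnot(inherits(state, "glyco_state"))
  cpp_compute_forces(state$pos,
                     as.integer(state$role == "solvent"),
                     as.integer(state$mobile),
                     bonds_mat(state), state$bonds[, "r0"], state$bonds[, "k"],
                     angles_mat(state), state$angles[, "kang"],
                     as.integer(state$tethers[, "i"]),
                     teth_xyz(state), state$tethers[, "k"],
                     state$box, cfg$f_x, cfg$r_c,
                     contain = any(!state$mobile))
}

bonds_mat <- function(state) {
  matrix(as.integer(state$bonds[, c("i", "j")]), ncol = 2)
}
angles_mat <- function(state) {
  matrix(as.integer(state$angles[, c("i", "j", "k")]), ncol = 3)
}
teth_xyz <- function(state) {
  matrix(as.numeric(state$tethers[, c("x", "y", "z")]), ncol = 3)
}

run_steps <- function(state, cfg, n_steps, record_every, equil_steps = 0L,
                      thermostat = TRUE, seed = cfg$seed, t0 = state$time) {
  cpp_run(state$pos, state$vel, state$mass,
          as.integer(state$role == "solvent"), as.integer(state$mobile),
          bonds_mat(state), state$bonds[, "r0"], state$bonds[, "k"],
          angles_mat(state), state$angles[, "kang"],
          as.integer(state$tethers[, "i"]), teth_xyz(state),
          state$tethers[, "k"], state$box, cfg$f_x, cfg$r_c, cfg$dt,
          cfg$temperature, cfg$gamma, as.integer(n_steps),
          as.integer(record_every), as.integer(equil_steps), thermostat,
          any(!state$mobile), as.numeric(seed), t0)
}

#' One velocity-Verlet step
#'
#' Advances mobile particles by one step of size `cfg$dt` (positions wrapped
#' into the periodic x,y box; immobile particles untouched; time advanced by
#' `dt`). The thermostat is not applied; see [lowe_andersen_collide()].
#'
#' @inheritParams compute_forces
#' @return the advanced `glyco_state`.
#' @export
step_velocity_verlet <- function(state, cfg) {
  out <- run_steps(state, cfg, n_steps = 1L, record_every = 1L,
                   thermostat = FALSE)
  k <- length(out$times)
  state$pos <- out$positions[[k]]
  state$vel <- out$velocities[[k]]
  state$time <- state$time + cfg$dt
  state
}

#' One Lowe-Andersen thermostat sweep
#'
#' Each mobile pair within `r_c` undergoes, with probability `gamma * dt`,
#' a resampling of its relative velocity component along the pair axis from
#' the thermal distribution at the target temperature, applied symmetrically
#' so pair momentum is conserved exactly. Pairs are visited in sorted index
#' order from a single seeded stream, so the sweep is deterministic. The
#' update depends only on relative velocities (Galilean invariant).
#'
#' @inheritParams compute_forces
#' @param seed integer seed for the collision stream.
#' @return the state with updated velocities.
#' @export
lowe_andersen_collide <- function(state, cfg, seed = cfg$seed) {
  if (cfg$gamma * cfg$dt >= 1)
    stop("gamma * dt >= 1: collision probability is not a probability")
  if (cfg$gamma == 0) return(state)
  state$vel <- cpp_lowe_andersen(state$pos, state$vel, state$mass,
                                 as.integer(state$mobile), state$box,
                                 cfg$r_c, cfg$gamma, cfg$dt,
                                 cfg$temperature, as.numeric(seed))
  state
}

#' Run a full simulation
#'
#' Builds the system, runs `cfg$n_equil` thermostatted zero-force
#' equilibration steps, then `cfg$n_steps` production steps with the body
#' force on, recording every `cfg$record_interval` steps (the state at the
#' start of production is frame 1). Identical configuration + seed gives
#' bit-identical trajectories. The returned trajectory carries a unit-scale
#' map (1 length unit = 1 nm, 1 time unit = 1 ps by default) and a per-frame
#' log of mean solvent x-velocity and kinetic temperature.
#'
#' @param cfg a [sim_config()].
#' @param units named numeric vector `c(length_nm = ..., time_ps = ...)`.
#' @return a `glyco_trajectory`.
#' @export
run_simulation <- function(cfg, units = c(length_nm = 1, time_ps = 1)) {
  validate_config(cfg)
  state <- build_system(cfg)
  out <- run_steps(state, cfg, n_steps = cfg$n_steps,
                   record_every = max(cfg$record_interval, 1L),
                   equil_steps = cfg$n_equil, thermostat = TRUE,
                   seed = cfg$seed + 7919)
  frames <- lapply(seq_along(out$times), function(k)
    list(pos = out$positions[[k]], vel = out$velocities[[k]]))
  traj <- list(times = as.numeric(out$times), frames = frames,
               species = species_code(state$role),
               topology = state_topology(state), box = state$box,
               units = units,
               log = data.frame(time = as.numeric(out$times),
                                mean_vx = out$mean_vx,
                                kinetic_T = out$kinetic_T))
  class(traj) <- "glyco_trajectory"
  traj
}

species_code <- function(role) {
  c(solvent = "S", wall = "W", ceiling = "X", core = "P", chain = "G")[role]
}

#' @export
print.glyco_trajectory <- function(x, ...) {
  cat(sprintf("glyco_trajectory: %d frames x %d particles, t in [%g, %g]\n",
              length(x$frames), nrow(x$frames[[1]]$pos), min(x$times),
              max(x$times)))
  cat(sprintf("  box %s; units: %s\n", paste(signif(x$box, 4), collapse = " x "),
              paste(names(x$units), x$units, sep = "=", collapse = ", ")))
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

solvent_idx <- function(traj) which(traj$topology$role == "solvent")

#' Kinetic temperature of a state
#'
#' \eqn{T = \sum_i m_i |v_i|^2 / (3 N k_B)} over mobile particles (k_B = 1).
#'
#' @param state a `glyco_state`.
#' @return scalar temperature in reduced units.
#' @export
kinetic_temperature <- function(state) {
  m <- state$mobile
  sum(state$mass[m] * rowSums(state$vel[m, , drop = FALSE]^2)) / (3 * sum(m))
}
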