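#' Simulation configuration
#'
#' Assemble and validate the parameter set of the coarse-grained microflow
#' simulator. The simulator works in reduced units (\eqn{\epsilon = \sigma =
#' m = k_B = 1}); the trajectory it produces carries an explicit unit-scale
#' map (defaults: 1 length unit = 1 nm, 1 time unit = 1 ps) so downstream
#' analyses can report physical units.
#'
#' The default geometry places a frozen wall lattice (lipid-bilayer stand-in)
#' at z = 0 and a frozen ceiling lattice (graphene stand-in) at z = Lz, with
#' `n_cores` stiff vertical oligomers anchored in the wall, each bearing
#' `chains_per_core` flexible tethered chains, immersed in `n_solvent`
#' solvent beads driven by a constant x-direction body force.
#'
#' @param Lx,Ly,Lz box edge lengths (sigma). x and y are periodic.
#' @param n_solvent number of solvent beads.
#' @param n_cores number of anchored core oligomers: 0 (no-brush control),
#'   1 or 3.
#' @param chains_per_core flexible chains tethered at each core apex.
#' @param beads_per_chain beads per flexible chain.
#' @param core_beads beads per stiff core oligomer.
#' @param f_x constant body force on each solvent bead, +x direction
#'   (reduced force units).
#' @param temperature thermostat target temperature (reduced, k_B = 1).
#' @param gamma Lowe-Andersen pair collision rate (1/time). `gamma * dt`
#'   must be < 1.
#' @param r_c pair interaction / thermostat cut-off (sigma). The repulsive
#'   force itself is truncated at the WCA minimum, min(r_c, 2^(1/6)).
#' @param dt integration time step (reduced time).
#' @param n_steps number of production steps.
#' @param record_interval record a frame every this many steps; must divide
#'   `n_steps` when `n_steps > 0`.
#' @param n_equil thermostatted zero-force equilibration steps prepended to
#'   production (not recorded).
#' @param seed integer seed controlling packing, initial velocities and the
#'   thermostat stream. Identical configurations and seeds give
#'   bit-identical trajectories.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(Lx = 10, Ly = 10, Lz = 20, n_solvent = 200,
#'                   n_cores = 1, beads_per_chain = 5, n_steps = 10,
#'                   record_interval = 5)
#' @export
sim_config <- function(Lx = 26, Ly = 26, Lz = 60, n_solvent = 16000,
                       n_cores = 3, chains_per_core = 6, beads_per_chain = 20,
                       core_beads = 6, f_x = 0.05, temperature = 1,
                       gamma = 2, r_c = 1.3, dt = 0.005, n_steps = 500000,
                       record_interval = 1000, n_equil = 5000, seed = 1L) {
  cfg <- list(Lx = Lx, Ly = Ly, Lz = Lz, n_solvent = as.integer(n_solvent),
              n_cores = as.integer(n_cores),
              chains_per_core = as.integer(chains_per_core),
              beads_per_chain = as.integer(beads_per_chain),
              core_beads = as.integer(core_beads), f_x = f_x,
              temperature = temperature, gamma = gamma, r_c = r_c, dt = dt,
              n_steps = as.integer(n_steps),
              record_interval = as.integer(record_interval),
              n_equil = as.integer(n_equil), seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  pos <- c("Lx", "Ly", "Lz", "temperature", "r_c", "dt")
  for (p in pos) {
    if (!is.finite(cfg[[p]]) || cfg[[p]] <= 0)
      stop(sprintf("config field '%s' must be strictly positive", p))
  }
  for (p in c("n_solvent", "chains_per_core", "beads_per_chain", "core_beads")) {
    if (cfg[[p]] < 1) stop(sprintf("config field '%s' must be >= 1", p))
  }
  if (cfg$f_x < 0) stop("body force f_x must be >= 0")
  if (cfg$gamma < 0) stop("collision rate gamma must be >= 0")
  if (cfg$gamma * cfg$dt >= 1)
    stop("gamma * dt >= 1: pair collision probability is not a probability")
  if (!cfg$n_cores %in% c(0L, 1L, 3L))
    stop("n_cores must be 0 (control), 1 or 3")
  if (cfg$n_steps < 0 || cfg$n_equil < 0)
    stop("step counts must be non-negative")
  if (cfg$n_steps > 0) {
    if (cfg$record_interval < 1 || cfg$n_steps %% cfg$record_interval != 0)
      stop("record_interval must divide n_steps")
  }
  # crude capacity check before packing is attempted
  vol <- cfg$Lx * cfg$Ly * max(cfg$Lz - 2, 1)
  if (cfg$n_solvent / vol > 0.85)
    stop(sprintf("n_solvent too large for box: requested density %.2f per sigma^3",
                 cfg$n_solvent / vol))
  invisible(cfg)
}

#' Desk-scale preset configuration
#'
#' A scaled-down configuration that preserves the reference geometry's
#' proportions (regions spanning 12/60, 36/60 and 50/60 of the box height,
#' so the "flow" region stays clear of the ceiling boundary layer; the
#' chain brush tops out inside the dendritic region) while running in
#' seconds on one CPU. Used by the test-suite and acceptance script for
#' seed-replicated qualitative checks.
#'
#' @param seed integer seed.
#' @param n_cores 0 (control), 1 or 3.
#' @param n_steps,record_interval production length (scaled down by
#'   default; stated in the methods vignette).
#' @return a [sim_config()].
#' @export
desk_preset <- function(seed = 1L, n_cores = 3L, n_steps = 12000L,
                        record_interval = 40L) {
  sim_config(Lx = 12, Ly = 12, Lz = 36, n_solvent = 1950,
             n_cores = n_cores, chains_per_core = 6, beads_per_chain = 10,
             core_beads = 7, f_x = 0.08, temperature = 1, gamma = 2,
             r_c = 1.3, dt = 0.005, n_steps = n_steps,
             record_interval = record_interval, n_equil = 1500, seed = seed)
}

#' @rdname desk_preset
#' @export
desk_regions <- function() partition_regions(0, c(7.2, 21.6, 30))

#' @export
print.sim_config <- function(x, ...) {
  cat("Coarse-grained microflow configuration (reduced units)\n")
  cat(sprintf("  box %g x %g x %g, %d solvent beads\n", x$Lx, x$Ly, x$Lz,
              x$n_solvent))
  cat(sprintf("  %d core(s) x %d chains x %d beads; f_x = %g, T = %g\n",
              x$n_cores, x$chains_per_core, x$beads_per_chain, x$f_x,
              x$temperature))
  cat(sprintf("  dt = %g, %d steps (record every %d), %d equilibration, seed %d\n",
              x$dt, x$n_steps, x$record_interval, x$n_equil, x$seed))
  invisible(x)
}
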