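# Fixtures are built in code; no binary data anywhere.

# a quick, cheap configuration for simulator unit tests
tiny_config <- function(seed = 1L, n_cores = 1L, n_steps = 200L,
                        record_interval = 20L, f_x = 0.02, ...) {
  sim_config(Lx = 8, Ly = 8, Lz = 14, n_solvent = 250, n_cores = n_cores,
             chains_per_core = 6, beads_per_chain = 4, core_beads = 3,
             f_x = f_x, n_steps = n_steps, record_interval = record_interval,
             n_equil = 200L, seed = seed, ...)
}

# hand-built trajectory: `frames` is a list of list(pos, vel); all particles
# default to solvent role
make_traj <- function(frames, times = seq_along(frames), box = c(10, 10, 10),
                      roles = NULL) {
  n <- nrow(frames[[1]]$pos)
  if (is.null(roles)) roles <- rep("solvent", n)
  topo <- data.frame(index = seq_len(n), role = roles,
                     chain_id = NA_integer_, chain_pos = NA_integer_,
                     anchor = NA_integer_, mass = 1)
  traj <- list(times = as.numeric(times), frames = frames,
               species = rep("S", n), topology = topo, box = box,
               units = c(length_nm = 1, time_ps = 1), log = NULL)
  class(traj) <- "glyco_trajectory"
  traj
}

# frame of particles on a regular z-filling grid with velocity field vf(x,y,z)
grid_frame <- function(box, nx = 6, ny = 6, nz = 20, vf) {
  g <- expand.grid(x = (seq_len(nx) - 0.5) * box[1] / nx,
                   y = (seq_len(ny) - 0.5) * box[2] / ny,
                   z = (seq_len(nz) - 0.5) * box[3] / nz)
  pos <- as.matrix(g)
  vel <- t(apply(pos, 1, function(p) vf(p[1], p[2], p[3])))
  list(pos = pos, vel = vel)
}

# minimal free state (no walls, no bonds) for integrator-level tests
free_state <- function(pos, vel = NULL, box = c(50, 50, 50),
                       role = "solvent") {
  pos <- matrix(pos, ncol = 3)
  if (is.null(vel)) vel <- matrix(0, nrow(pos), 3)
  n <- nrow(pos)
  st <- list(pos = pos, vel = matrix(vel, ncol = 3), mass = rep(1, n),
             role = rep(role, n), mobile = rep(TRUE, n),
             chain_id = rep(NA_integer_, n), chain_pos = rep(NA_integer_, n),
             anchor = rep(NA_integer_, n),
             bonds = matrix(numeric(0), 0, 4,
                            dimnames = list(NULL, c("i", "j", "r0", "k"))),
             angles = matrix(numeric(0), 0, 4,
                             dimnames = list(NULL, c("i", "j", "k", "kang"))),
             tethers = matrix(numeric(0), 0, 5,
                              dimnames = list(NULL, c("i", "x", "y", "z", "k"))),
             box = box, time = 0)
  class(st) <- "glyco_state"
  st
}

add_bond <- function(state, i, j, r0, k) {
  state$bonds <- rbind(state$bonds, c(i, j, r0, k))
  colnames(state$bonds) <- c("i", "j", "r0", "k")
  state
}

add_tether <- function(state, i, xyz, k) {
  state$tethers <- rbind(state$tethers, c(i, xyz, k))
  colnames(state$tethers) <- c("i", "x", "y", "z", "k")
  state
}
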