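#' Build the initial particle system
#'
#' Construct the initial [SystemState][build_system] for a configuration:
#' a frozen wall lattice at z = 0 and a frozen ceiling lattice at z = Lz
#' (both immobile, regular in-plane lattices with a small deterministic
#' z-corrugation so they exert traction on the fluid), `n_cores` stiff
#' vertical oligomers tethered into the wall, `chains_per_core` flexible
#' chains bonded to each core apex, and `n_solvent` solvent beads placed by
#' random sequential insertion with minimum pair distance `0.8 * r_c` and
#' Maxwell-Boltzmann velocities at the target temperature. Deterministic for
#' a fixed `cfg$seed`.
#'
#' Particle roles: `"solvent"`, `"wall"`, `"ceiling"`, `"core"`, `"chain"`.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `glyco_state`: positions, velocities, masses,
#'   roles, mobility flags, bond/angle/tether tables, box and time.
#' @export
build_system <- function(cfg) {
  validate_config(cfg)
  set.seed(cfg$seed)

  lat <- function(z0, role) {
    nx <- max(2L, round(cfg$Lx)); ny <- max(2L, round(cfg$Ly))
    g <- expand.grid(i = seq_len(nx) - 1L, j = seq_len(ny) - 1L)
    # checkerboard corrugation: frozen but rough, so the lattice exchanges
    # x-momentum with the fluid (a smooth frozen plane would be free-slip)
    zjit <- 0.25 * ifelse((g$i + g$j) %% 2 == 0, 1, -1)
    cbind((g$i + 0.5) * cfg$Lx / nx, (g$j + 0.5) * cfg$Ly / ny, z0 + zjit)
  }
  wall <- lat(0, "wall")
  ceil <- lat(cfg$Lz, "ceiling")

  pos <- rbind(wall, ceil)
  role <- c(rep("wall", nrow(wall)), rep("ceiling", nrow(ceil)))
  chain_id <- rep(NA_integer_, nrow(pos))
  chain_pos <- rep(NA_integer_, nrow(pos))
  anchor <- rep(NA_integer_, nrow(pos))
  bonds <- list(); angles <- list(); tethers <- list()

  core_x <- switch(as.character(cfg$n_cores),
                   "0" = numeric(0),
                   "1" = cfg$Lx / 2,
                   "3" = cfg$Lx / 2 + c(-cfg$Lx / 4, 0, cfg$Lx / 4))
  chain_counter <- 0L
  for (ic in seq_along(core_x)) {
    xc <- core_x[ic]; yc <- cfg$Ly / 2
    base <- nrow(pos)
    core_idx <- base + seq_len(cfg$core_beads)
    pos <- rbind(pos, cbind(xc, yc, seq_len(cfg$core_beads)))
    role <- c(role, rep("core", cfg$core_beads))
    chain_id <- c(chain_id, rep(NA_integer_, cfg$core_beads))
    chain_pos <- c(chain_pos, rep(NA_integer_, cfg$core_beads))
    anchor <- c(anchor, rep(NA_integer_, cfg$core_beads))
    if (cfg$core_beads > 1) {
      for (k in seq_len(cfg$core_beads - 1))
        bonds[[length(bonds) + 1]] <- c(core_idx[k], core_idx[k + 1], 1, 400)
    }
    if (cfg$core_beads > 2) {
      for (k in seq_len(cfg$core_beads - 2))
        angles[[length(angles) + 1]] <- c(core_idx[k], core_idx[k + 1],
                                          core_idx[k + 2], 100)
    }
    # two tethers fix both position and orientation of the stiff core
    tethers[[length(tethers) + 1]] <- c(core_idx[1], xc, yc, 1, 400)
    if (cfg$core_beads > 1)
      tethers[[length(tethers) + 1]] <- c(core_idx[2], xc, yc, 2, 100)
    apex <- core_idx[cfg$core_beads]
    apex_z <- cfg$core_beads
    for (jc in seq_len(cfg$chains_per_core)) {
      chain_counter <- chain_counter + 1L
      phi <- 2 * pi * (jc - 1) / cfg$chains_per_core
      dirv <- c(cos(phi) * sin(pi / 4.5), sin(phi) * sin(pi / 4.5), cos(pi / 4.5))
      kseq <- seq_len(cfg$beads_per_chain)
      cpos <- cbind(xc + dirv[1] * kseq, yc + dirv[2] * kseq,
                    apex_z + dirv[3] * kseq)
      cpos[, 3] <- pmin(cpos[, 3], cfg$Lz - 1.5)
      first <- nrow(pos) + 1L
      pos <- rbind(pos, cpos)
      role <- c(role, rep("chain", cfg$beads_per_chain))
      chain_id <- c(chain_id, rep(chain_counter, cfg$beads_per_chain))
      chain_pos <- c(chain_pos, kseq)
      anchor <- c(anchor, rep(apex, cfg$beads_per_chain))
      bonds[[length(bonds) + 1]] <- c(apex, first, 1, 100)
      if (cfg$beads_per_chain > 1) {
        for (k in seq_len(cfg$beads_per_chain - 1))
          bonds[[length(bonds) + 1]] <- c(first + k - 1L, first + k, 1, 100)
      }
    }
  }

  # chains fanning out from neighbouring cores can intersect at construction;
  # push any polymer bead pair apart to a safe separation before solvation
  # (deterministic; the bonded terms re-relax lengths during equilibration)
  mob_poly <- which(role %in% c("core", "chain"))
  if (length(mob_poly) > 1)
    pos[mob_poly, ] <- resolve_overlaps(pos[mob_poly, , drop = FALSE],
                                        cfg$Lx, cfg$Ly, minsep = 0.6)

  mindist <- 0.8 * cfg$r_c
  solv <- cpp_place_solvent(cfg$n_solvent, c(cfg$Lx, cfg$Ly, cfg$Lz),
                            zlo = 0.8, zhi = cfg$Lz - 0.8, existing = pos,
                            mindist = mindist,
                            seed = cfg$seed * 2654435761 %% 2^31,
                            max_tries = 500L)
  first_s <- nrow(pos) + 1L
  pos <- rbind(pos, solv)
  role <- c(role, rep("solvent", cfg$n_solvent))
  chain_id <- c(chain_id, rep(NA_integer_, cfg$n_solvent))
  chain_pos <- c(chain_pos, rep(NA_integer_, cfg$n_solvent))
  anchor <- c(anchor, rep(NA_integer_, cfg$n_solvent))

  n <- nrow(pos)
  mobile <- !(role %in% c("wall", "ceiling"))
  mass <- rep(1, n)
  vel <- matrix(0, n, 3)
  nm <- sum(mobile)
  vel[mobile, ] <- matrix(stats::rnorm(3 * nm, sd = sqrt(cfg$temperature)),
                          nm, 3)
  # remove net drift so initial mean flow is zero
  vel[mobile, ] <- sweep(vel[mobile, , drop = FALSE], 2,
                         colMeans(vel[mobile, , drop = FALSE]))

  bonds <- if (length(bonds)) do.call(rbind, bonds) else matrix(0, 0, 4)
  angles <- if (length(angles)) do.call(rbind, angles) else matrix(0, 0, 4)
  tethers <- if (length(tethers)) do.call(rbind, tethers) else matrix(0, 0, 5)
  colnames(bonds) <- c("i", "j", "r0", "k")
  colnames(angles) <- c("i", "j", "k", "kang")
  colnames(tethers) <- c("i", "x", "y", "z", "k")
  dimnames(pos) <- NULL

  state <- list(pos = pos, vel = vel, mass = mass, role = role,
                mobile = mobile, chain_id = chain_id, chain_pos = chain_pos,
                anchor = anchor, bonds = bonds, angles = angles,
                tethers = tethers, box = c(cfg$Lx, cfg$Ly, cfg$Lz), time = 0)
  class(state) <- "glyco_state"
  state
}

#' @export
print.glyco_state <- function(x, ...) {
  cat(sprintf("glyco_state: %d particles (%s) at t = %g\n", nrow(x$pos),
              paste(sprintf("%s:%d", names(table(x$role)), table(x$role)),
                    collapse = ", "), x$time))
  invisible(x)
}

resolve_overlaps <- function(p, Lx, Ly, minsep = 0.6, iters = 500) {
  n <- nrow(p)
  for (it in seq_len(iters)) {
    moved <- FALSE
    for (i in seq_len(n - 1)) {
      dx <- p[(i + 1):n, 1] - p[i, 1]; dx <- dx - Lx * round(dx / Lx)
      dy <- p[(i + 1):n, 2] - p[i, 2]; dy <- dy - Ly * round(dy / Ly)
      dz <- p[(i + 1):n, 3] - p[i, 3]
      d2 <- dx^2 + dy^2 + dz^2
      close <- which(d2 < minsep^2)
      for (c in close) {
        j <- i + c
        d <- sqrt(d2[c])
        u <- if (d > 1e-9) c(dx[c], dy[c], dz[c]) / d
             else c(cos(j), sin(j), 0.5) / sqrt(1.25)  # deterministic tie-break
        push <- (minsep - d) / 2 + 0.01
        p[i, ] <- p[i, ] - u * push
        p[j, ] <- p[j, ] + u * push
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  p
}

state_topology <- function(state) {
  data.frame(index = seq_along(state$role), role = state$role,
              chain_id = state$chain_id, chain_pos = state$chain_pos,
              anchor = state$anchor, mass = state$mass)
}
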