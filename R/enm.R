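#' Build a harmonic (elastic) network from a structure
#'
#' Connects every pair of beads whose initial C-alpha separation is within
#' `cutoff` by a harmonic spring with the given uniform stiffness and rest
#' length equal to the build-time distance, so the starting configuration
#' sits exactly at the potential-energy minimum (PE = 0).
#'
#' @param structure a `protein_structure`.
#' @param cutoff contact cutoff in Angstrom (default 10).
#' @param stiffness spring constant in kcal/mol/A^2 (default 1.0).
#' @return a `harmonic_network`: masses, positions, and a spring table
#'   (i, j, k, r0) with i < j, plus a sparse incidence matrix used by the
#'   integrator.
#' @export
build_network <- function(structure, cutoff = 10, stiffness = 1.0) {
  ed_assert(cutoff > 0, "enerdiss_input_error", "cutoff must be > 0")
  ed_assert(stiffness > 0, "enerdiss_input_error", "stiffness must be > 0")
  xyz <- structure$xyz
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  pair <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  springs <- data.frame(i = pair[, 1], j = pair[, 2],
                        k = stiffness, r0 = d[pair])
  springs <- springs[order(springs$i, springs$j), , drop = FALSE]
  rownames(springs) <- NULL
  ed_assert(all(springs$r0 > 0), "enerdiss_input_error",
            "coincident beads within cutoff (r0 = 0)")
  deg <- tabulate(c(springs$i, springs$j), nbins = n)
  if (any(deg == 0)) {
    warning(sprintf("%d isolated bead(s) with no springs (indices %s): they can never respond",
                    sum(deg == 0),
                    paste(which(deg == 0), collapse = ", ")))
  }
  net <- list(mass = structure$residues$mass,
              xyz0 = xyz,
              springs = springs,
              source_id = structure$source_id)
  net$incidence <- spring_incidence(n, springs)
  class(net) <- "harmonic_network"
  net
}

# n x nspring sparse incidence matrix: +1 at i, -1 at j, so
# t(B) %*% pos = per-spring displacement vectors x_i - x_j.
spring_incidence <- function(n, springs) {
  ns <- nrow(springs)
  if (ns == 0) return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                           x = numeric(0), dims = c(n, 0)))
  Matrix::sparseMatrix(i = c(springs$i, springs$j),
                       j = rep(seq_len(ns), 2),
                       x = rep(c(1, -1), each = ns),
                       dims = c(n, ns))
}

#' @export
print.harmonic_network <- function(x, ...) {
  cat(sprintf("harmonic_network: %d beads, %d springs\n",
              length(x$mass), nrow(x$springs)))
  invisible(x)
}

#' Rescale spring stiffness around chosen residues
#'
#' Multiplies the stiffness of every spring incident to the listed
#' residues by `factor`.  This is the package's surrogate for a point
#' mutation: a locally softened (factor < 1) or stiffened network.
#'
#' @param network a `harmonic_network`.
#' @param residues residue indices whose incident springs are rescaled.
#' @param factor positive stiffness multiplier (default 0.5).
#' @return the modified network.
#' @export
soften_network <- function(network, residues, factor = 0.5) {
  ed_assert(factor > 0, "enerdiss_input_error", "factor must be > 0")
  n <- length(network$mass)
  ed_assert(all(residues %in% seq_len(n)), "enerdiss_index_error",
            "unknown residue index in 'residues'")
  hit <- network$springs$i %in% residues | network$springs$j %in% residues
  network$springs$k[hit] <- network$springs$k[hit] * factor
  network
}

#' Simulation configuration
#'
#' Bundles integrator and thermostat settings.  Defaults mirror the
#' dissipation-phase conditions: 1 fs timestep, frames saved every 10
#' steps, 310 K.
#'
#' @param timestep integration step, fs.
#' @param n_steps number of dissipation (NVE) steps.
#' @param save_interval save a frame every this many steps.
#' @param temperature target temperature, K.
#' @param seed integer RNG seed for velocity initialization.
#' @param cutoff contact cutoff, Angstrom.
#' @param stiffness spring constant, kcal/mol/A^2.
#' @param equilibration_steps thermostatted steps before the NVE phase.
#' @param rescale_interval thermostat rescaling interval during
#'   equilibration, in steps.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(timestep = 1, n_steps = 1000,
                              save_interval = 10, temperature = 310,
                              seed = 0, cutoff = 10, stiffness = 1.0,
                              equilibration_steps = 500,
                              rescale_interval = 50) {
  ed_assert(timestep > 0, "enerdiss_input_error", "timestep must be > 0")
  ed_assert(save_interval >= 1, "enerdiss_input_error",
            "save_interval must be >= 1")
  ed_assert(cutoff > 0, "enerdiss_input_error", "cutoff must be > 0")
  structure(list(timestep = timestep, n_steps = as.integer(n_steps),
                 save_interval = as.integer(save_interval),
                 temperature = temperature, seed = as.integer(seed),
                 cutoff = cutoff, stiffness = stiffness,
                 equilibration_steps = as.integer(equilibration_steps),
                 rescale_interval = as.integer(rescale_interval)),
            class = "simulation_config")
}

#' Draw a thermalized initial state
#'
#' Velocities come from the Maxwell-Boltzmann distribution at the given
#' temperature (per-component normal with variance kB*T/m), after which
#' the net linear momentum is removed.  Positions are the network's build
#' positions.  The same seed gives a bit-identical state.
#'
#' @param network a `harmonic_network`.
#' @param temperature kelvin; 0 gives exactly zero velocities.
#' @param seed integer RNG seed.
#' @return a `system_state`: positions, velocities (A/fs), time (fs).
#' @export
init_state <- function(network, temperature = 310, seed = 0) {
  ed_assert(temperature >= 0, "enerdiss_input_error",
            "temperature must be >= 0")
  n <- length(network$mass)
  if (temperature == 0) {
    vel <- matrix(0, n, 3)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    sd_v <- sqrt(.KB_INTERNAL * temperature / network$mass)
    vel <- matrix(stats::rnorm(3 * n), n, 3) * sd_v
    # remove net linear momentum so the molecule does not drift
    p <- colSums(vel * network$mass)
    vel <- sweep(vel, 2, p / sum(network$mass))
  }
  structure(list(pos = network$xyz0, vel = vel, time = 0),
            class = "system_state")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Forces in internal units (amu A fs^-2) and per-spring potential energies
# (internal units).  Returns list(force = n x 3, pe = nspring vector).
.forces <- function(network, pos) {
  B <- network$incidence
  d <- as.matrix(Matrix::crossprod(B, pos))        # nspring x 3, x_i - x_j
  r <- sqrt(rowSums(d * d))
  k_int <- network$springs$k * .KCAL_PER_MOL_INTERNAL
  stretch <- r - network$springs$r0
  coef <- k_int * stretch / r
  force <- -as.matrix(B %*% (coef * d))
  list(force = force, pe = 0.5 * k_int * stretch^2)
}

#' Per-residue energies of a state
#'
#' Each residue's energy is its kinetic energy plus half of every incident
#' spring's potential energy, so the vector sums exactly to the total
#' system energy.
#'
#' @param network a `harmonic_network`.
#' @param state a `system_state`.
#' @return numeric vector, kcal/mol per residue.
#' @export
per_residue_energy <- function(network, state) {
  ke_int <- 0.5 * network$mass * rowSums(state$vel^2)
  pe_s <- .forces(network, state$pos)$pe
  pe_res <- as.numeric(abs(network$incidence) %*% (0.5 * pe_s))
  (ke_int + pe_res) / .KCAL_PER_MOL_INTERNAL
}

# instantaneous kinetic temperature (K), 3N - 3 dof (momentum removed)
.kinetic_temperature <- function(network, vel) {
  ke <- 0.5 * sum(network$mass * vel^2)
  dof <- 3 * length(network$mass) - 3
  2 * ke / (dof * .KB_INTERNAL)
}

#' Scale the velocities of chosen residues
#'
#' The velocity vectors of the listed residues are multiplied by `factor`
#' (direction preserved), so their kinetic energy scales by exactly
#' factor^2; all other entries are untouched.  This is the kinetic-energy
#' perturbation standing in for ligand-binding energy input.
#'
#' @param state a `system_state`.
#' @param residues residue indices to perturb.
#' @param factor velocity multiplier f (> 0); f = 1 is a null control.
#' @return the perturbed `system_state`.
#' @export
apply_perturbation <- function(state, residues, factor) {
  ed_assert(length(residues) >= 1, "enerdiss_input_error",
            "need at least one perturbed residue")
  ed_assert(factor > 0, "enerdiss_input_error",
            "velocity factor must be > 0")
  n <- nrow(state$vel)
  ed_assert(all(residues >= 1 & residues <= n),
            "enerdiss_index_error", "perturbed residue index out of range")
  state$vel[residues, ] <- state$vel[residues, , drop = FALSE] * factor
  state
}

# velocity-Verlet core shared by equilibrate() and integrate().
# thermostat_every = 0 disables rescaling (NVE).
.vv_run <- function(network, state, n_steps, dt, save_interval = 0,
                    thermostat_every = 0, temperature = NA) {
  pos <- state$pos; vel <- state$vel
  m <- network$mass
  inv_m <- 1 / m
  f <- .forces(network, pos)
  acc <- f$force * inv_m
  frames <- NULL
  if (save_interval > 0) {
    n_frames <- n_steps %/% save_interval + 1L
    frames <- vector("list", n_frames)
    frames[[1]] <- list(pos = pos, vel = vel, time = state$time)
  }
  half_dt <- 0.5 * dt
  for (step in seq_len(n_steps)) {
    vel <- vel + half_dt * acc
    pos <- pos + dt * vel
    f <- .forces(network, pos)
    acc <- f$force * inv_m
    vel <- vel + half_dt * acc
    if (!all(is.finite(pos))) {
      ed_stop("enerdiss_integration_error",
              "non-finite coordinates at step %d", step)
    }
    if (thermostat_every > 0 && step %% thermostat_every == 0) {
      t_inst <- .kinetic_temperature(network, vel)
      if (t_inst > 0) vel <- vel * sqrt(temperature / t_inst)
    }
    if (save_interval > 0 && step %% save_interval == 0) {
      frames[[step %/% save_interval + 1L]] <-
        list(pos = pos, vel = vel, time = state$time + step * dt)
    }
  }
  final <- structure(list(pos = pos, vel = vel,
                          time = state$time + n_steps * dt),
                     class = "system_state")
  list(final = final, frames = frames)
}

#' Equilibrate a state with a deterministic rescaling thermostat
#'
#' Runs `config$equilibration_steps` of velocity-Verlet, rescaling all
#' velocities to the target temperature every `config$rescale_interval`
#' steps.  Deterministic given the input state, so paired runs branching
#' from the result remain exactly comparable.
#'
#' @param network a `harmonic_network`.
#' @param state a `system_state` (e.g. from [init_state()]).
#' @param config a `simulation_config`.
#' @return the equilibrated `system_state`.
#' @export
equilibrate <- function(network, state, config) {
  if (config$equilibration_steps == 0) return(state)
  .vv_run(network, state, config$equilibration_steps, config$timestep,
          save_interval = 0,
          thermostat_every = config$rescale_interval,
          temperature = config$temperature)$final
}

#' Microcanonical (NVE) integration with saved frames
#'
#' Velocity-Verlet at `config$timestep` for `config$n_steps` steps with no
#' thermostat; temperature and pressure float freely, as required for the
#' dissipation phase.  Frame 0 is the initial state; frames follow every
#' `config$save_interval` steps.  Deterministic: no randomness after
#' initialization.
#'
#' @param network a `harmonic_network`.
#' @param state starting `system_state`.
#' @param config a `simulation_config`.
#' @return list of frames, each `list(pos, vel, time)`.
#' @export
integrate_nve <- function(network, state, config) {
  .vv_run(network, state, config$n_steps, config$timestep,
          save_interval = config$save_interval)$frames
}

#' Total energy of a state (kcal/mol)
#' @param network a `harmonic_network`.
#' @param state a `system_state`.
#' @return total kinetic + potential energy in kcal/mol.
#' @export
total_energy <- function(network, state) {
  ke <- 0.5 * sum(network$mass * state$vel^2)
  pe <- sum(.forces(network, state$pos)$pe)
  (ke + pe) / .KCAL_PER_MOL_INTERNAL
}

# Build an energy_trace from saved frames.
.trace_from_frames <- function(network, frames, metadata) {
  energies <- vapply(frames, function(fr) {
    per_residue_energy(network,
                       structure(list(pos = fr$pos, vel = fr$vel),
                                 class = "system_state"))
  }, numeric(length(network$mass)))
  energies <- matrix(energies, nrow = length(network$mass))
  times <- vapply(frames, `[[`, numeric(1), "time")
  energy_trace(times, energies, metadata)
}

#' Per-residue energy time series
#'
#' @param times frame times in fs, strictly increasing.
#' @param energies residues x frames matrix, kcal/mol.
#' @param metadata free-form list (config echo, perturbation, ...).
#' @return an `energy_trace`.
#' @export
energy_trace <- function(times, energies, metadata = list()) {
  energies <- as.matrix(energies)
  ed_assert(length(times) == ncol(energies), "enerdiss_input_error",
            "column count must equal frame count")
  ed_assert(all(diff(times) > 0), "enerdiss_input_error",
            "frame times must be strictly increasing")
  structure(list(times = as.numeric(times), energies = energies,
                 metadata = metadata), class = "energy_trace")
}

#' @export
print.energy_trace <- function(x, ...) {
  cat(sprintf("energy_trace: %d residues x %d frames, t = %g..%g fs\n",
              nrow(x$energies), ncol(x$energies),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Run a paired perturbed/reference dissipation simulation
#'
#' Both runs start from the identical `initial_state`; the perturbed run
#' applies the velocity scaling at time 0 and nothing else differs, so
#' subtracting the reference trace isolates the perturbation's effect
#' exactly (bit-identical null for f = 1).
#'
#' @param network a `harmonic_network`.
#' @param initial_state a `system_state`, typically equilibrated.
#' @param residues perturbed residue indices.
#' @param factor velocity multiplier f.
#' @param config a `simulation_config`.
#' @return list with elements `perturbed` and `reference`, both
#'   `energy_trace`s on the identical time grid.
#' @export
run_pair <- function(network, initial_state, residues, factor, config) {
  meta_base <- list(config = unclass(config))
  pert_state <- apply_perturbation(initial_state, residues, factor)
  pert_frames <- integrate_nve(network, pert_state, config)
  ref_frames <- integrate_nve(network, initial_state, config)
  list(
    perturbed = .trace_from_frames(network, pert_frames,
      c(meta_base, list(perturbation = list(residues = residues,
                                            factor = factor)))),
    reference = .trace_from_frames(network, ref_frames,
      c(meta_base, list(perturbation = NULL))))
}
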