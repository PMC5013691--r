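# Thermostatted Langevin dynamics of the C-alpha network.

#' Langevin dynamics parameters
#'
#' The equation of motion per bead is `m a = F_spring - gamma m v + xi(t)`
#' with Gaussian white noise obeying the fluctuation-dissipation relation,
#' discretized per timestep to variance `2 gamma m kB T / dt` per force
#' component. Friction and noise together act as a thermostat.
#'
#' @param dt Timestep in fs (default 1).
#' @param temperature Bath temperature in K (default 300).
#' @param gamma Friction rate per particle in ps^-1 (default 50,
#'   solvent-like damping).
#' @param mass Residue mass in Da (default 100, the average amino acid).
#' @param seed Integer RNG seed.
#' @return List of class `bd_params`.
#' @export
bd_params <- function(dt = 1, temperature = 300, gamma = 50, mass = 100,
                      seed = 1L) {
  stopifnot(dt > 0, temperature >= 0, gamma >= 0, mass > 0)
  structure(list(dt = dt, temperature = temperature, gamma = gamma,
                 mass = mass, seed = as.integer(seed)),
            class = "bd_params")
}

#' Create a simulation state
#'
#' @param coords N x 3 coordinates in Angstrom.
#' @param velocities N x 3 velocities in A/fs; default zero.
#' @param step Step counter.
#' @return List of class `sim_state`.
#' @export
sim_state <- function(coords, velocities = NULL, step = 0L) {
  coords <- .as_coords(coords)
  if (is.null(velocities)) velocities <- matrix(0, nrow(coords), 3L)
  stopifnot(all(is.finite(coords)), all(is.finite(velocities)),
            all(dim(velocities) == dim(coords)))
  structure(list(coords = coords, velocities = velocities,
                 step = as.integer(step)),
            class = "sim_state")
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Each component ~ `N(0, kB T / m)` in internal units (A/fs).
#'
#' @param n Number of particles.
#' @param temperature Kelvin.
#' @param mass Da.
#' @return N x 3 velocity matrix.
#' @export
maxwell_velocities <- function(n, temperature, mass = 100) {
  sig <- sqrt(.kB * temperature * .kcal_to_internal / mass)
  matrix(rnorm(3L * n, 0, sig), n, 3L)
}

#' Advance the Langevin dynamics by one (or more) BBK steps
#'
#' Velocity-Verlet discretization of the Langevin equation in the BBK form:
#' half kick with the old force and noise, drift, new force and noise, half
#' kick scaled by `1/(1 + gamma dt/2)`. Reproducible through R's RNG:
#' `set.seed()` before the call fixes the trajectory.
#'
#' @param state A [sim_state()].
#' @param topology An [build_ed_enm()] topology.
#' @param params A [bd_params()].
#' @param n_steps Number of steps to advance (default 1).
#' @return Updated [sim_state()].
#' @export
langevin_step <- function(state, topology, params, n_steps = 1L) {
  stopifnot(inherits(state, "sim_state"))
  out <- cpp_run_langevin(state$coords, state$velocities, topology$pairs,
                          topology$K, topology$d0, as.integer(n_steps),
                          params$dt, params$gamma * 1e-3, params$temperature,
                          params$mass, as.integer(n_steps), FALSE)
  sim_state(out$coords, out$velocities, state$step + as.integer(n_steps))
}

#' Run unbiased Langevin dynamics
#'
#' Populates the conformational space around the build structure with the
#' thermostat active throughout; no demon, no bias.
#'
#' @param model A [ca_model()] giving the starting coordinates.
#' @param topology An [build_ed_enm()] topology.
#' @param params A [bd_params()]; `params$seed` fixes the run.
#' @param n_steps Total number of integration steps.
#' @param stride Store every stride-th frame.
#' @param remove_com Re-centre coordinates at each stored frame (leaves
#'   internal dynamics untouched; off by default).
#' @param start_velocities Optional N x 3 start velocities; default
#'   Maxwell-Boltzmann at `params$temperature`.
#' @return List of class `bd_run`: `trajectory` ([ca_trajectory()]),
#'   `kinetic_temperature` (per-frame, K), `mean_kinetic_temperature` (K,
#'   averaged over every step), and the final `state`.
#' @export
run_unbiased <- function(model, topology, params = bd_params(),
                         n_steps, stride = 100L, remove_com = FALSE,
                         start_velocities = NULL) {
  stopifnot(n_steps >= 1L, stride >= 1L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(params$seed)
  if (is.null(start_velocities))
    start_velocities <- maxwell_velocities(model$n, params$temperature,
                                           params$mass)
  out <- cpp_run_langevin(model$coords, start_velocities, topology$pairs,
                          topology$K, topology$d0, as.integer(n_steps),
                          params$dt, params$gamma * 1e-3, params$temperature,
                          params$mass, as.integer(stride), remove_com)
  nf <- dim(out$frames)[3L]
  frames <- lapply(seq_len(nf), function(k) out$frames[, , k])
  structure(list(trajectory = ca_trajectory(frames,
                                            steps = seq_len(nf) * stride),
                 kinetic_temperature = as.numeric(out$temp_frame),
                 mean_kinetic_temperature = out$mean_kinetic_temperature,
                 state = sim_state(out$coords, out$velocities,
                                   as.integer(n_steps))),
            class = "bd_run")
}

#' @export
print.bd_run <- function(x, ...) {
  cat("bd_run: ", length(x$trajectory$frames), " frames, <T_kin> = ",
      sprintf("%.1f", x$mean_kinetic_temperature), " K\n", sep = "")
  invisible(x)
}
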