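#' Langevin velocity-Verlet integration
#'
#' Advances the system with the velocity-Verlet integrator coupled to a
#' Langevin thermostat (friction `gamma`, target temperature `k_BT`).  The
#' exact Ornstein-Uhlenbeck velocity update is applied once per step after
#' the two deterministic half-kicks, so `gamma = 0` recovers plain symplectic
#' velocity-Verlet (the NVE limit).  Frames (monomer or all-particle
#' positions, wrap counters, potential energy and instantaneous kinetic
#' temperature) are recorded every `sample_stride` steps, including the
#' initial state.  A run is bit-reproducible from `(state, spec, seed)`.
#'
#' A bond stretched to the FENE maximum or a particle escaping the wall (both
#' symptoms of an unstable time step) raise an integration-failure error
#' naming the step; the trajectory up to the last stable frame is attached to
#' the condition as `partial`.
#'
#' @param state a [particle_state()].
#' @param spec a [system_spec()].
#' @param n_steps number of time steps (0 gives a single-frame trajectory).
#' @param sample_stride steps between recorded frames (default 1000).
#' @param seed integer seed for the thermostat noise stream.
#' @param record `"monomers"` (default), `"all"`, or `"none"` (final state
#'   only).
#' @param topology a [ring_topology()].
#' @return An object of class `trajectory`: recorded frames plus the final
#'   full [particle_state()] in `$final_state`.
#' @export
integrate_dynamics <- function(state, spec, n_steps, sample_stride = 1000,
                               seed = spec$seed, record = c("monomers", "all", "none"),
                               topology = ring_topology(spec$n_monomers)) {
  record <- match.arg(record)
  n_steps <- as.integer(n_steps)
  stopifnot(n_steps >= 0)
  eng <- engine_inputs(state, spec, topology)
  res <- .cpp_run_dynamics(eng$positions, eng$velocities, eng$images,
                           eng$species0, eng$par,
                           n_steps, as.integer(sample_stride), as.double(seed),
                           record != "monomers")
  n_mobile <- nrow(state$positions)
  final_state <- particle_state(
    res$positions[seq_len(n_mobile), , drop = FALSE],
    res$velocities[seq_len(n_mobile), , drop = FALSE],
    state$species,
    res$images[seq_len(n_mobile)])
  frames <- res$frames
  frame_images <- res$frame_images
  if (record == "none") { frames <- list(); frame_images <- list() }
  traj <- structure(list(
    frames = frames,
    frame_images = frame_images,
    steps = if (record == "none") integer(0) else res$steps,
    potential_energy = res$potential_energy,
    kinetic_temperature = res$kinetic_temperature,
    sample_stride = as.integer(sample_stride),
    species_recorded = if (record == "all") state$species else
      rep(1L, spec$n_monomers),
    record = record,
    spec = spec,
    seed = as.integer(seed),
    final_state = final_state), class = "trajectory")
  if (!res$ok)
    stop(errorCondition(
      sprintf("integration failure: %s (step %d)", res$message, res$fail_step),
      class = c(if (grepl("overstretch", res$message)) "crowdring_overstretch",
                "crowdring_integration_failure"),
      partial = traj))
  traj
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames (stride %d), %d recorded particles\n",
              length(x$frames), x$sample_stride,
              if (length(x$frames)) nrow(x$frames[[1]]) else 0L))
  cat(sprintf("  spec: N = %d, phi_c = %g, D = %g, L = %g (%s)\n",
              x$spec$n_monomers, x$spec$phi_c, x$spec$geometry$diameter,
              x$spec$geometry$length, x$spec$geometry$mode))
  invisible(x)
}

#' Advance the system by a single Langevin step
#'
#' One velocity-Verlet/Langevin step; deterministic given `(state, seed)`.
#'
#' @inheritParams integrate_dynamics
#' @return The updated [particle_state()].
#' @export
langevin_step <- function(state, spec, seed = spec$seed,
                          topology = ring_topology(spec$n_monomers)) {
  integrate_dynamics(state, spec, n_steps = 1L, sample_stride = 1L,
                     seed = seed, record = "none", topology = topology)$final_state
}

#' Wrap longitudinal coordinates into the periodic box
#'
#' Maps each z into `[0, L)` and updates the per-particle image counters so
#' unwrapped coordinates `z + image * L` are recovered exactly.
#'
#' @param state a [particle_state()].
#' @param geometry a [cylinder_geometry()] in periodic mode.
#' @export
apply_periodic <- function(state, geometry) {
  if (geometry$mode != "periodic")
    stop("apply_periodic called on a capped geometry")
  L <- geometry$length
  z <- state$positions[, 3]
  shift <- floor(z / L)
  state$positions[, 3] <- z - shift * L
  state$images <- state$images + as.integer(shift)
  state
}

#' Instantaneous kinetic temperature
#'
#' Equipartition estimate \eqn{T = \sum_i m_i v_i^2 / (3 n)} in units of
#' \eqn{\epsilon/k_B}.
#'
#' @param state a [particle_state()].
#' @param spec a [system_spec()] (for the per-species masses).
#' @export
kinetic_temperature <- function(state, spec = NULL) {
  mass <- if (is.null(spec)) rep(1, nrow(state$positions)) else
    unname(spec$dynamics$mass)[pmin(state$species, 2L)]
  sum(mass * rowSums(state$velocities^2)) / (3 * nrow(state$velocities))
}
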