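## Relaxed chain sizes R0 = R(phi_c = 0), measured once per (N, D) and cached.
## Cylinder lengths for production runs are set as multiples of R0, so the
## lookup has to be available before any system is built.  All entries were
## measured with measure_r0() on this package's own engine at phi_c = 0
## (periodic box L = 3 R0, 4 replicates, 2e6 steps, first 20% discarded);
## replicate standard errors are below 0.1 a.
.r0_table <- data.frame(
  n = c(135L, 135L, 135L, 60L, 40L, 20L),
  d = c(5,    4,    3,    5,   5,   5),
  r0 = c(29.9, 33.9, 39.3, 13.2, 8.8, 4.3)
)

#' Relaxed longitudinal chain size R0
#'
#' Returns the cached equilibrium longitudinal span \eqn{R_0 = R(\phi_c = 0)}
#' for a ring of `n` monomers in a cylinder of diameter `d`.  Exact cached
#' entries are preferred; for other parameter combinations an extrapolation
#' from the nearest cached diameter (linear in N, de Gennes blob scaling
#' \eqn{R \propto D^{-2/3}} in diameter) is returned with a warning.
#'
#' @param n ring length N.
#' @param d cylinder diameter, in a.
#' @return R0 in units of a.
#' @seealso [measure_r0()] to measure and cache a new entry.
#' @export
r0_lookup <- function(n, d) {
  hit <- .r0_table$n == n & abs(.r0_table$d - d) < 1e-9
  if (any(hit)) return(.r0_table$r0[which(hit)[1]])
  ref <- .r0_table[which.min(abs(.r0_table$d - d) * 100 + abs(.r0_table$n - n)), ]
  est <- ref$r0 * (n / ref$n) * (ref$d / d)^(2 / 3)
  warning(sprintf(
    "no cached R0 for (N = %d, D = %g); extrapolating %0.1f a from (N = %d, D = %g)",
    n, d, est, ref$n, ref$d))
  est
}

#' Measure the relaxed chain size for a parameter combination
#'
#' Runs crowder-free replicates in a long periodic cylinder and returns the
#' frame- and replicate-averaged longitudinal span.  Used to populate the R0
#' cache consulted by [r0_lookup()].
#'
#' @param n ring length N.
#' @param d cylinder diameter, in a.
#' @param length cylinder length for the measurement (default: three times the
#'   current lookup estimate).
#' @param n_steps steps per replicate.
#' @param replicates number of independent replicates.
#' @param sample_stride steps between recorded frames.
#' @param discard_fraction initial fraction of frames dropped as equilibration.
#' @param seed base seed; replicate k uses `seed + k - 1`.
#' @return A list with the mean `r0`, its standard error `se`, and the
#'   per-replicate means.
#' @export
measure_r0 <- function(n, d, length = NULL, n_steps = 2e6, replicates = 4,
                       sample_stride = 1000, discard_fraction = 0.2, seed = 1) {
  if (is.null(length))
    length <- 3 * suppressWarnings(r0_lookup(n, d))
  per_rep <- vapply(seq_len(replicates), function(k) {
    spec <- system_spec(n_monomers = n, phi_c = 0,
                        geometry = cylinder_geometry(d, length),
                        seed = seed + k - 1)
    sys <- build_system(spec)
    traj <- integrate_dynamics(sys$state, spec, n_steps = n_steps,
                               sample_stride = sample_stride,
                               seed = spec$seed)
    obs <- frame_observables(traj, sys$topology, spec$geometry,
                             discard_fraction = discard_fraction)
    mean(obs$R)
  }, numeric(1))
  list(r0 = mean(per_rep),
       se = if (replicates > 1) stats::sd(per_rep) / sqrt(replicates) else 0,
       replicates = per_rep)
}
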