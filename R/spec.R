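#' Pairwise interaction table
#'
#' Builds the symmetric 3x3 tables of WCA length and energy parameters over
#' the three species (monomer, crowder, wall-forming bead).  Lengths follow
#' the Lorentz mixing rule \eqn{\sigma_{12} = (\sigma_{11}+\sigma_{22})/2};
#' the monomer-wall length equals the monomer diameter (wall beads are of the
#' same kind as monomers).  All energies default to \eqn{\epsilon = 1} except
#' the monomer-wall strength `eps13`, the tuning parameter that coarse-grains
#' chromosome-membrane interactions such as transertion.
#'
#' @param eps13 monomer-wall interaction strength, in units of eps.
#' @param a monomer diameter (the length unit; default 1).
#' @param a_c crowder diameter, in units of `a`.
#' @param eps monomer-monomer interaction strength (the energy unit).
#' @return An object of class `interaction_table` with matrices `sigma` and
#'   `epsilon` (species order: monomer, crowder, wall).
#' @export
interaction_table <- function(eps13 = 1, a = 1, a_c = 0.3 * a, eps = 1) {
  stopifnot(a > 0, a_c > 0, eps > 0, eps13 > 0)
  sp <- c("monomer", "crowder", "wall")
  sigma <- matrix(0, 3, 3, dimnames = list(sp, sp))
  sigma[1, 1] <- a
  sigma[2, 2] <- a_c
  sigma[3, 3] <- a
  sigma[1, 2] <- sigma[2, 1] <- (a + a_c) / 2
  sigma[1, 3] <- sigma[3, 1] <- a
  sigma[2, 3] <- sigma[3, 2] <- (a_c + a) / 2
  epsilon <- matrix(eps, 3, 3, dimnames = list(sp, sp))
  epsilon[1, 3] <- epsilon[3, 1] <- eps13
  out <- structure(list(sigma = sigma, epsilon = epsilon), class = "interaction_table")
  validate_interaction_table(out)
  out
}

validate_interaction_table <- function(x) {
  stopifnot(inherits(x, "interaction_table"))
  if (!isTRUE(all.equal(x$sigma, t(x$sigma))) ||
      !isTRUE(all.equal(x$epsilon, t(x$epsilon))))
    stop("interaction table must be symmetric")
  if (any(x$sigma <= 0) || any(x$epsilon <= 0))
    stop("interaction table entries must be positive")
  if (abs(x$sigma[1, 2] - (x$sigma[1, 1] + x$sigma[2, 2]) / 2) > 1e-12)
    stop("sigma[1,2] must satisfy the mixing rule (sigma11 + sigma22)/2")
  invisible(x)
}

#' FENE bond parameters
#'
#' @param k spring constant, in eps/sigma^2 (default 30, the standard
#'   bead-spring value).
#' @param r0 maximum bond extension, in sigma (default 1.5).
#' @export
bond_params <- function(k = 30, r0 = 1.5) {
  stopifnot(k > 0, r0 > 0)
  structure(list(k = k, r0 = r0), class = "bond_params")
}

#' Langevin dynamics parameters
#'
#' Reduced units throughout: the time unit is \eqn{\tau_0 = \sigma\sqrt{m/\epsilon}}
#' and temperature is measured in \eqn{\epsilon/k_B} (the default `temperature
#' = 1` corresponds to the simulated room temperature).
#'
#' @param dt integration time step, in tau0.
#' @param gamma friction constant, in 1/tau0.
#' @param temperature thermostat target k_B T, in eps.
#' @param mass per-species masses `c(monomer, crowder)`, in m.
#' @export
dynamics_params <- function(dt = 0.002, gamma = 0.1, temperature = 1,
                            mass = c(monomer = 1, crowder = 1)) {
  stopifnot(dt > 0, gamma >= 0, temperature > 0, all(mass > 0))
  if (length(mass) == 1) mass <- c(monomer = mass, crowder = mass)
  structure(list(dt = dt, gamma = gamma, temperature = temperature,
                 mass = mass), class = "dynamics_params")
}

#' Cylinder geometry
#'
#' The cylinder of diameter `D` bounds the accessible region for particle
#' centers: the smooth wall exerts the WCA repulsion on the effective gap
#' \eqn{h = (D/2 + \sigma_{i3}) - \rho}, so a particle whose center sits on
#' the nominal surface \eqn{\rho = D/2} is exactly at wall contact
#' (\eqn{h = \sigma_{i3}}, energy \eqn{\epsilon_{i3}}) and the rescaled radial
#' coordinate \eqn{r = 2\rho/D} spans approximately \eqn{[0, 1]}.  In capped
#' mode the same law acts on the axial gaps at the two end caps and no
#' longitudinal wrapping occurs.  `wall_model = "beads"` replaces the analytic
#' barrel by an explicit cylindrical lattice of wall beads (species 3) of
#' spacing `bead_spacing`, handled through the ordinary pair path; the end
#' caps remain analytic.
#'
#' @param diameter cylinder diameter D, in a.
#' @param length cylinder length L, in a.
#' @param mode `"periodic"` (longitudinal periodic boundary) or `"capped"`.
#' @param wall_model `"smooth"` (analytic, default) or `"beads"`.
#' @param bead_spacing lattice spacing of the bead-built wall, in a.
#' @export
cylinder_geometry <- function(diameter, length, mode = c("periodic", "capped"),
                              wall_model = c("smooth", "beads"),
                              bead_spacing = 0.7) {
  mode <- match.arg(mode)
  wall_model <- match.arg(wall_model)
  stopifnot(diameter > 2, length > 0, bead_spacing > 0)
  structure(list(diameter = diameter, length = length, mode = mode,
                 wall_model = wall_model, bead_spacing = bead_spacing),
            class = "cylinder_geometry")
}

#' Full system specification
#'
#' Collects every physical parameter of one simulation: the ring (N monomers
#' of diameter `a`), the crowders (diameter `a_c`, volume fraction `phi_c`
#' relative to the nominal cylinder volume \eqn{\pi (D/2)^2 L}), the
#' interaction tables, bond and dynamics constants, the confining geometry,
#' and the seed from which every random choice of the run is derived.
#'
#' When `geometry` is omitted, an open (periodic) cylinder of diameter 5a and
#' length `3 * r0_lookup(N, D)` is used — three times the relaxed chain size,
#' so the chain cannot interact with its periodic images.
#'
#' @param n_monomers ring length N (>= 3).
#' @param monomer_diameter monomer diameter a (the length unit).
#' @param crowder_diameter crowder diameter a_c (default 0.3 a).
#' @param phi_c crowder volume fraction, in [0, 0.4].
#' @param eps13 monomer-wall interaction strength (used when `interactions`
#'   is not supplied).
#' @param interactions an [interaction_table()].
#' @param bonds a [bond_params()].
#' @param dynamics a [dynamics_params()].
#' @param geometry a [cylinder_geometry()], or `NULL` for the default.
#' @param seed integer seed for system construction and dynamics.
#' @return An object of class `system_spec`.
#' @export
system_spec <- function(n_monomers = 135, monomer_diameter = 1,
                        crowder_diameter = 0.3 * monomer_diameter,
                        phi_c = 0, eps13 = 1,
                        interactions = interaction_table(eps13 = eps13,
                                                         a = monomer_diameter,
                                                         a_c = crowder_diameter),
                        bonds = bond_params(), dynamics = dynamics_params(),
                        geometry = NULL, seed = 1L) {
  if (is.null(geometry)) {
    d <- 5 * monomer_diameter
    geometry <- cylinder_geometry(diameter = d,
                                  length = 3 * r0_lookup(n_monomers, d))
  }
  out <- structure(list(
    n_monomers = as.integer(n_monomers),
    monomer_diameter = monomer_diameter,
    crowder_diameter = crowder_diameter,
    phi_c = phi_c,
    interactions = interactions,
    bonds = bonds,
    dynamics = dynamics,
    geometry = geometry,
    seed = as.integer(seed)), class = "system_spec")
  validate_system_spec(out)
  out
}

validate_system_spec <- function(spec) {
  stopifnot(inherits(spec, "system_spec"))
  if (spec$n_monomers < 3) stop("need at least 3 monomers to close a ring")
  if (spec$phi_c < 0 || spec$phi_c > 0.4)
    stop("phi_c must lie in [0, 0.4]")
  if (spec$crowder_diameter > spec$monomer_diameter)
    stop("crowders must not be larger than monomers")
  if (spec$bonds$r0 <= 2^(1 / 6) * spec$monomer_diameter)
    stop("FENE r0 must exceed the WCA minimum 2^(1/6) sigma")
  if (spec$geometry$diameter <= 2 * spec$monomer_diameter)
    stop("cylinder diameter must exceed 2 monomer diameters")
  validate_interaction_table(spec$interactions)
  invisible(spec)
}

#' @export
print.system_spec <- function(x, ...) {
  g <- x$geometry
  cat("Ring-polymer system specification\n")
  cat(sprintf("  ring:      N = %d monomers, diameter a = %g\n",
              x$n_monomers, x$monomer_diameter))
  cat(sprintf("  crowders:  a_c = %g, phi_c = %g\n",
              x$crowder_diameter, x$phi_c))
  cat(sprintf("  cylinder:  D = %g, L = %g (%s, %s wall)\n",
              g$diameter, g$length, g$mode, g$wall_model))
  cat(sprintf("  eps13 = %g, k_BT = %g, dt = %g tau0, gamma = %g/tau0\n",
              x$interactions$epsilon[1, 3], x$dynamics$temperature,
              x$dynamics$dt, x$dynamics$gamma))
  cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}

#' Ring topology and opposing-arm pairing
#'
#' The ring is split into two arms at monomers 1 and `floor(N/2) + 1`
#' (1-based), mirroring the origin/terminus split of a circular bacterial
#' chromosome.  Monomer `i + 1` on one arm is paired with its contour-opposed
#' partner `N - i + 1` on the other arm; the two split monomers are excluded,
#' giving `floor(N/2) - 1` pairs.
#'
#' @param n ring length N.
#' @return An object of class `ring_topology` with a `bonds` matrix (N x 2)
#'   and an `arm_pairs` matrix.
#' @export
ring_topology <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 3)
  bonds <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  half <- n %/% 2L
  i <- seq_len(half - 1L)
  arm_pairs <- cbind(left = i + 1L, right = n - i + 1L)
  structure(list(n = n, bonds = bonds, arm_pairs = arm_pairs,
                 split = c(1L, half + 1L)),
            class = "ring_topology")
}

#' Particle state
#'
#' @param positions n x 3 matrix of coordinates, in a.
#' @param velocities n x 3 matrix, in a/tau0.
#' @param species character or integer vector (`"monomer"`/`"crowder"`).
#' @param images integer longitudinal wrap counters (periodic mode).
#' @export
particle_state <- function(positions, velocities = NULL, species, images = NULL) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3)
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  if (is.character(species))
    species <- match(species, c("monomer", "crowder", "wall"))
  species <- as.integer(species)
  stopifnot(length(species) == n, all(species %in% 1:3))
  if (is.null(images)) images <- integer(n)
  structure(list(positions = positions, velocities = as.matrix(velocities),
                 species = species, images = as.integer(images)),
            class = "particle_state")
}

#' Validate a particle state against a system specification
#'
#' Checks the particle-count, containment and bond-length invariants: the
#' monomer count matches N, every center lies inside the accessible cylinder
#' cross-section (within the thermal penetration depth of the wall), and all
#' bonded distances are below the FENE maximum extension.
#'
#' @param state a [particle_state()].
#' @param spec a [system_spec()].
#' @param topology a [ring_topology()]; defaults to the ring implied by `spec`.
#' @export
validate_state <- function(state, spec, topology = ring_topology(spec$n_monomers)) {
  n_mono <- sum(state$species == 1L)
  if (n_mono != spec$n_monomers)
    stop(sprintf("state has %d monomers but spec expects %d", n_mono,
                 spec$n_monomers))
  g <- spec$geometry
  mobile <- state$species %in% 1:2
  sw <- ifelse(state$species[mobile] == 1L,
               spec$interactions$sigma[1, 3], spec$interactions$sigma[2, 3])
  rho <- sqrt(rowSums(state$positions[mobile, 1:2, drop = FALSE]^2))
  if (any(rho > g$diameter / 2 + 0.5 * sw))
    stop("particle center outside the accessible cylinder cross-section")
  if (g$mode == "capped") {
    z <- state$positions[mobile, 3]
    if (any(z < -0.5 * sw) || any(z > g$length + 0.5 * sw))
      stop("particle center outside the capped cylinder")
  }
  d <- bond_lengths(state, spec, topology)
  if (any(d >= spec$bonds$r0))
    stop("bonded distance at or beyond the FENE maximum extension")
  invisible(TRUE)
}

bond_lengths <- function(state, spec, topology = ring_topology(spec$n_monomers)) {
  p <- state$positions
  b <- topology$bonds
  d <- p[b[, 1], , drop = FALSE] - p[b[, 2], , drop = FALSE]
  if (spec$geometry$mode == "periodic") {
    L <- spec$geometry$length
    d[, 3] <- d[, 3] - L * round(d[, 3] / L)
  }
  sqrt(rowSums(d^2))
}
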