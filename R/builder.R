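#' Closed helical ring configuration
#'
#' Builds the initial ring as a folded double helix: the chain is folded in
#' half into two strands that run side by side (offset vertically by about
#' one bead diameter), and the folded pair is wound along a helix of radius
#' about `0.25 * D` whose pitch and rise are chosen so every bond sits close
#' to one bond length and the coil fits between the caps.  Both strands wind
#' in the same sense and never cross; the two fold points become the arm
#' split beads.  The construction is deterministic.
#'
#' @param n ring length N (>= 3).
#' @param geometry a [cylinder_geometry()].
#' @param bond_length target bond length, in a (default 1).
#' @return n x 3 matrix of monomer coordinates.
#' @export
build_ring <- function(n, geometry, bond_length = 1) {
  n <- as.integer(n)
  stopifnot(n >= 3)
  b <- bond_length
  D <- geometry$diameter
  L <- geometry$length
  z_center <- L / 2
  if (n <= 5) {
    # degenerate helix: planar regular polygon
    ang <- 2 * pi * (seq_len(n) - 1) / n
    circ <- b / (2 * sin(pi / n))
    if (circ > D / 2) stop("cylinder too narrow for a planar ring of this size")
    pos <- cbind(circ * cos(ang), circ * sin(ang), rep(z_center, n))
    return(check_built_ring(pos, n, geometry, b))
  }
  # Folded double helix: the ring is folded in half into two strands that
  # run side by side, offset vertically by one rung spacing `s`, and the
  # folded pair is wound along a single helix of radius r.  Both strands
  # then wind in the same sense, so they never cross; the two fold points
  # become the arm split beads.  For odd N the extra bead sits at one fold.
  s <- 0.95 * b                     # rung (strand-strand) spacing
  m <- n %/% 2L                     # beads per strand
  dz <- 0.5 * b                     # axial rise per bead along a strand
  h_avail <- 0.88 * L - s
  if ((m - 1) * dz > h_avail) dz <- h_avail / (m - 1)
  if (dz < 0.15 * b)
    stop("no feasible helical layout: cylinder too short for this N")
  chord <- sqrt(b^2 - dz^2)
  radius <- 0.25 * D
  alpha <- 2 * asin(min(0.999, chord / (2 * radius)))
  if (2 * pi * dz / alpha < 1.9 * b) {    # winding pitch must clear the pair
    alpha <- 2 * pi * dz / (1.9 * b)
    radius <- chord / (2 * sin(alpha / 2))
    if (radius > 0.38 * D)
      stop("no feasible helical layout: cylinder too narrow for this N")
  }
  j <- 0:(m - 1)
  height <- (m - 1) * dz + s
  z0 <- z_center - height / 2
  up <- cbind(radius * cos(j * alpha), radius * sin(j * alpha), z0 + j * dz)
  dn <- up
  dn[, 3] <- dn[, 3] + s
  if (n %% 2L == 1L) {
    # extra apex bead bridging the top of the two strands
    dth <- 2 * asin(min(0.999, sqrt(b^2 - (s / 2)^2) / (2 * radius)))
    apex_ang <- (m - 1) * alpha + dth
    apex <- c(radius * cos(apex_ang), radius * sin(apex_ang),
              z0 + (m - 1) * dz + s / 2)
    pos <- rbind(up, apex, dn[m:1, , drop = FALSE])
  } else {
    pos <- rbind(up, dn[m:1, , drop = FALSE])
  }
  check_built_ring(pos, n, geometry, b)
}

check_built_ring <- function(pos, n, geometry, b) {
  d <- pos - pos[c(2:n, 1), ]
  bl <- sqrt(rowSums(d^2))
  if (any(bl < 0.9 * b - 1e-9) || any(bl > 1.1 * b + 1e-9))
    stop("helical construction produced bond lengths outside [0.9, 1.1] sigma")
  dm <- as.matrix(stats::dist(pos))
  diag(dm) <- Inf
  if (min(dm) < 0.85 * b - 1e-9)
    stop("helical construction produced bead overlaps")
  rho <- sqrt(rowSums(pos[, 1:2, drop = FALSE]^2))
  if (any(rho > geometry$diameter / 2))
    stop("helical ring does not fit inside the cylinder")
  pos
}

#' Number of crowders at a target volume fraction
#'
#' \eqn{N_c = \mathrm{round}(\phi_c \pi (D/2)^2 L / ((\pi/6) a_c^3))}, using
#' the nominal cylinder volume (no accessible-volume correction; the
#' convention is echoed into run metadata since it shifts the effective
#' crowding slightly).
#'
#' @param phi_c crowder volume fraction, in [0, 0.4].
#' @param geometry a [cylinder_geometry()].
#' @param a_c crowder diameter, in a.
#' @export
crowder_count <- function(phi_c, geometry, a_c = 0.3) {
  stopifnot(phi_c >= 0, phi_c <= 0.4)
  v_cyl <- pi * (geometry$diameter / 2)^2 * geometry$length
  v_c <- pi / 6 * a_c^3
  as.integer(round(phi_c * v_cyl / v_c))
}

#' Randomly place crowders in the accessible cylinder volume
#'
#' Random sequential insertion: candidate centers are drawn uniformly over
#' the nominal cross-section (area-uniform in radius) and the cylinder
#' length, and rejected if they overlap an existing particle deeper than
#' `0.9` of the pair contact distance.  Insertion failure after `max_attempts
#' * n` candidate draws raises a packing error naming the achieved count.
#'
#' @param n number of crowders to place.
#' @param geometry a [cylinder_geometry()].
#' @param existing matrix of existing particle coordinates (may have 0 rows).
#' @param existing_contact per-existing-particle contact distance with a
#'   crowder (scalar or vector).
#' @param a_c crowder diameter.
#' @param seed integer seed.
#' @param max_attempts attempts allowed per crowder.
#' @return n x 3 matrix of crowder coordinates.
#' @export
place_crowders <- function(n, geometry, existing = NULL, existing_contact = 0.65,
                           a_c = 0.3, seed = 1, max_attempts = 200) {
  n <- as.integer(n)
  if (n == 0) return(matrix(numeric(0), 0, 3))
  if (is.null(existing)) existing <- matrix(numeric(0), 0, 3)
  existing <- as.matrix(existing)
  contact2 <- rep_len((0.9 * existing_contact)^2, nrow(existing))
  res <- .cpp_place_crowders(n, geometry$diameter / 2, geometry$length,
                             geometry$mode == "periodic", existing, contact2,
                             0.9 * a_c, as.double(seed),
                             as.integer(max_attempts))
  if (res$achieved < n)
    stop(errorCondition(
      sprintf("crowder packing failed: placed %d of %d requested",
              res$achieved, n),
      class = "crowdring_packing_error"))
  res$positions
}

#' Assemble the full initial system
#'
#' Builds the helical ring, draws Maxwell-Boltzmann velocities at the
#' thermostat temperature, and inserts crowders at the requested volume
#' fraction.  Up to \eqn{\phi_c = 0.25} crowders are placed by direct random
#' sequential insertion at full size.  Above that (where sequential insertion
#' saturates) an inflation protocol is used: crowders are inserted at 70% of
#' their diameter and grown back to full size over `1e4` Langevin relaxation
#' steps, after which velocities are redrawn.
#'
#' @param spec a [system_spec()].
#' @return `list(state = particle_state, topology = ring_topology)`.
#' @export
build_system <- function(spec) {
  validate_system_spec(spec)
  g <- spec$geometry
  topo <- ring_topology(spec$n_monomers)
  ring <- build_ring(spec$n_monomers, g, bond_length = spec$monomer_diameter)
  n_c <- crowder_count(spec$phi_c, g, spec$crowder_diameter)
  inflate <- spec$phi_c > 0.25 && n_c > 0
  scale0 <- if (inflate) 0.7 else 1
  a_c_eff <- scale0 * spec$crowder_diameter
  contact_mc <- (spec$monomer_diameter + a_c_eff) / 2
  crowders <- place_crowders(n_c, g, existing = ring,
                             existing_contact = contact_mc,
                             a_c = a_c_eff, seed = spec$seed)
  pos <- rbind(ring, crowders)
  species <- c(rep(1L, spec$n_monomers), rep(2L, n_c))
  vel <- draw_velocities(species, spec, seed = spec$seed + 1L)
  state <- particle_state(pos, vel, species)
  if (inflate) {
    state <- inflate_crowders(state, spec, scale0 = scale0,
                              n_relax_steps = 1e4, seed = spec$seed + 2L)
    state$velocities <- draw_velocities(species, spec, seed = spec$seed + 3L)
  }
  validate_state(state, spec, topo)
  list(state = state, topology = topo)
}

draw_velocities <- function(species, spec, seed) {
  mass <- unname(spec$dynamics$mass)[pmin(species, 2L)]
  kT <- spec$dynamics$temperature
  with_local_seed(seed, {
    matrix(stats::rnorm(3 * length(species)), ncol = 3) * sqrt(kT / mass)
  })
}

# Grow undersized crowders back to full diameter in stages, relaxing with the
# Langevin engine between stages.
inflate_crowders <- function(state, spec, scale0 = 0.7, n_relax_steps = 1e4,
                             seed = 1) {
  stages <- seq(scale0, 1, length.out = 21)[-1]
  steps_per_stage <- max(1L, as.integer(round(n_relax_steps / length(stages))))
  for (i in seq_along(stages)) {
    spec_eff <- spec
    spec_eff$crowder_diameter <- stages[i] * spec$crowder_diameter
    spec_eff$interactions <- interaction_table(
      eps13 = spec$interactions$epsilon[1, 3],
      a = spec$monomer_diameter,
      a_c = spec_eff$crowder_diameter,
      eps = spec$interactions$epsilon[1, 1])
    traj <- integrate_dynamics(state, spec_eff, n_steps = steps_per_stage,
                               sample_stride = steps_per_stage,
                               seed = seed + i, record = "none")
    state <- traj$final_state
  }
  state
}

#' Small deterministic test systems
#'
#' Named fixtures with frozen coordinates: `"dimer"` (two unbonded monomers at
#' contact distance sigma on the cylinder axis), `"triangle-ring"` (N = 3
#' planar ring), `"ring20"` (N = 20 helical ring, D = 5a) and
#' `"ring20+crowders"` (the same ring plus 50 crowders).  Each returns
#' `list(state, topology, spec)` as [build_system()] does.
#'
#' @param name fixture name.
#' @export
make_fixture <- function(name) {
  geo20 <- cylinder_geometry(5, 3 * r0_lookup(20L, 5))
  switch(name,
    "dimer" = {
      # two free monomers at separation sigma on the axis; empty bond list
      spec <- system_spec(n_monomers = 3, phi_c = 0, geometry = geo20, seed = 1)
      pos <- rbind(c(0, 0, geo20$length / 2),
                   c(0, 0, geo20$length / 2 + 1))
      state <- particle_state(pos, species = c(1L, 1L))
      topo <- structure(list(n = 2L, bonds = matrix(integer(0), 0, 2),
                             arm_pairs = matrix(integer(0), 0, 2),
                             split = integer(0)), class = "ring_topology")
      spec$n_monomers <- 2L
      list(state = state, topology = topo, spec = spec)
    },
    "triangle-ring" = {
      spec <- system_spec(n_monomers = 3, phi_c = 0, geometry = geo20, seed = 1)
      sys <- build_system(spec)
      c(sys, list(spec = spec))
    },
    "ring20" = {
      spec <- system_spec(n_monomers = 20, phi_c = 0, geometry = geo20, seed = 1)
      sys <- build_system(spec)
      c(sys, list(spec = spec))
    },
    "ring20+crowders" = {
      spec <- system_spec(n_monomers = 20, phi_c = 0, geometry = geo20, seed = 1)
      sys <- build_system(spec)
      crowders <- place_crowders(50, geo20, existing = sys$state$positions,
                                 existing_contact = 0.65, a_c = 0.3, seed = 7)
      pos <- rbind(sys$state$positions, crowders)
      species <- c(sys$state$species, rep(2L, 50))
      vel <- draw_velocities(species, spec, seed = 11)
      list(state = particle_state(pos, vel, species),
           topology = sys$topology, spec = spec)
    },
    stop(sprintf("unknown fixture '%s'", name))
  )
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.  Keeps construction deterministic per spec
# seed without clobbering the session RNG.
with_local_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}
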