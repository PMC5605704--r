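#' Weeks-Chandler-Andersen pair energy
#'
#' The purely repulsive WCA potential
#' \deqn{U(r) = 4\epsilon_{ij}\left[(\sigma_{ij}/r)^{12} -
#'   (\sigma_{ij}/r)^{6} + 1/4\right]} for \eqn{r < 2^{1/6}\sigma_{ij}} and
#' exactly zero beyond the cutoff, so that both the energy and the force are
#' continuous there.
#'
#' @param r center-to-center distance(s), > 0.
#' @param i,j species of the pair: 1 (monomer), 2 (crowder) or 3 (wall), or
#'   the equivalent names.
#' @param table an [interaction_table()].
#' @return Energy in units of eps (vectorized over `r`).
#' @export
wca_energy <- function(r, i, j, table) {
  i <- species_index(i); j <- species_index(j)
  if (any(r <= 0)) stop("pair distance must be positive")
  sig <- table$sigma[i, j]
  eps <- table$epsilon[i, j]
  u <- numeric(length(r))
  inside <- r < 2^(1 / 6) * sig
  if (any(inside)) {
    s6 <- (sig / r[inside])^6
    u[inside] <- 4 * eps * (s6^2 - s6 + 0.25)
  }
  u
}

#' WCA pair force
#'
#' Analytic gradient of [wca_energy()]: the force exerted on the particle at
#' displacement `r_vec` from its partner, directed along `r_vec` (repulsive).
#'
#' @param r_vec displacement vector (length 3) from partner to particle.
#' @inheritParams wca_energy
#' @return Force vector (length 3), in eps/a.
#' @export
wca_force <- function(r_vec, i, j, table) {
  i <- species_index(i); j <- species_index(j)
  r2 <- sum(r_vec^2)
  if (r2 <= 0) stop("zero-length displacement has no defined force direction")
  sig <- table$sigma[i, j]
  eps <- table$epsilon[i, j]
  if (r2 >= (2^(1 / 6) * sig)^2) return(c(0, 0, 0))
  s6 <- (sig^2 / r2)^3
  (24 * eps * (2 * s6^2 - s6) / r2) * r_vec
}

#' FENE bond energy
#'
#' \deqn{U(r) = -\tfrac{1}{2} k r_0^2 \ln\left[1 - (r/r_0)^2\right]} — zero at
#' zero extension, strictly increasing, and divergent at the maximum extension
#' `r0`.  A distance at or beyond `r0` raises a bond-overstretch error (the
#' usual symptom of an unstable time step) rather than being clamped.
#'
#' @param r bond length(s), in `[0, r0)`.
#' @param bonds a [bond_params()].
#' @export
fene_energy <- function(r, bonds) {
  if (any(r < 0)) stop("bond length must be non-negative")
  if (any(r >= bonds$r0)) stop_overstretch(max(r), bonds$r0)
  -0.5 * bonds$k * bonds$r0^2 * log(1 - (r / bonds$r0)^2)
}

#' FENE bond force
#'
#' Force on the particle at displacement `r_vec` from its bonded partner:
#' attractive, of magnitude \eqn{k r / (1 - (r/r_0)^2)}.
#'
#' @param r_vec displacement vector from partner to particle.
#' @param bonds a [bond_params()].
#' @export
fene_force <- function(r_vec, bonds) {
  r2 <- sum(r_vec^2)
  if (r2 >= bonds$r0^2) stop_overstretch(sqrt(r2), bonds$r0)
  -(bonds$k / (1 - r2 / bonds$r0^2)) * r_vec
}

stop_overstretch <- function(r, r0, step = NULL) {
  msg <- sprintf("FENE bond overstretched: r = %.4f >= r0 = %.4f", r, r0)
  if (!is.null(step)) msg <- sprintf("%s (step %d)", msg, step)
  stop(errorCondition(msg, class = c("crowdring_overstretch", "crowdring_integration_failure")))
}

stop_integration <- function(msg, step = NULL) {
  if (!is.null(step) && step >= 0) msg <- sprintf("%s (step %d)", msg, step)
  stop(errorCondition(msg, class = "crowdring_integration_failure"))
}

species_index <- function(s) {
  if (is.character(s)) s <- match(s, c("monomer", "crowder", "wall"))
  s <- as.integer(s)
  if (is.na(s) || s < 1 || s > 3) stop("species must be monomer, crowder or wall")
  s
}

#' Confining-wall interaction for one particle
#'
#' Smooth wall (default): the WCA law with parameters \eqn{(\epsilon_{i3},
#' \sigma_{i3})} acts on the effective radial gap \eqn{h = (D/2 + \sigma_{i3})
#' - \rho}, so that a center on the nominal surface \eqn{\rho = D/2} is at
#' wall contact; the force is purely radial and points inward.  In capped
#' mode the same law acts on the axial gap at each cap.  With `wall_model =
#' "beads"` the barrel interaction is instead the sum of WCA pair terms with
#' the explicit wall-bead lattice from [wall_beads()] (caps stay analytic).
#'
#' @param position coordinate vector (length 3).
#' @param species particle species (1/"monomer" or 2/"crowder").
#' @param geometry a [cylinder_geometry()].
#' @param table an [interaction_table()].
#' @return `list(energy =, force =)`.
#' @export
wall_interaction <- function(position, species, geometry, table) {
  s <- species_index(species)
  sw <- table$sigma[s, 3]
  cutoff <- 2^(1 / 6) * sw
  rho <- sqrt(sum(position[1:2]^2))
  if (rho >= geometry$diameter / 2 + sw)
    stop_integration("particle outside the confining cylinder")
  energy <- 0
  force <- c(0, 0, 0)
  if (geometry$wall_model == "smooth") {
    h <- (geometry$diameter / 2 + sw) - rho
    if (h < cutoff && rho > 1e-12) {
      energy <- energy + wca_scalar(h, sw, table$epsilon[s, 3])
      # dU/dh < 0 inside the cutoff; dh/drho = -1, so F_rho = dU/dh (inward)
      force[1:2] <- force[1:2] + wca_dudr(h, sw, table$epsilon[s, 3]) *
        position[1:2] / rho
    }
  } else {
    wb <- wall_beads(geometry, table$sigma[1, 3])
    for (k in seq_len(nrow(wb))) {
      dr <- position - wb[k, ]
      if (geometry$mode == "periodic") {
        L <- geometry$length
        dr[3] <- dr[3] - L * round(dr[3] / L)
      }
      r <- sqrt(sum(dr^2))
      if (r < cutoff) {
        energy <- energy + wca_scalar(r, sw, table$epsilon[s, 3])
        force <- force - wca_dudr(r, sw, table$epsilon[s, 3]) * dr / r
      }
    }
  }
  if (geometry$mode == "capped") {
    for (h in c(position[3] + sw, geometry$length - position[3] + sw)) {
      if (h < 0.25 * sw) stop_integration("particle outside the capped cylinder")
      if (h < cutoff) energy <- energy + wca_scalar(h, sw, table$epsilon[s, 3])
    }
    hlo <- position[3] + sw
    hhi <- geometry$length - position[3] + sw
    if (hlo < cutoff) force[3] <- force[3] - wca_dudr(hlo, sw, table$epsilon[s, 3])
    if (hhi < cutoff) force[3] <- force[3] + wca_dudr(hhi, sw, table$epsilon[s, 3])
  }
  list(energy = energy, force = force)
}

wca_scalar <- function(r, sig, eps) {
  if (r >= 2^(1 / 6) * sig) return(0)
  s6 <- (sig / r)^6
  4 * eps * (s6^2 - s6 + 0.25)
}

wca_dudr <- function(r, sig, eps) {
  if (r >= 2^(1 / 6) * sig) return(0)
  s6 <- (sig / r)^6
  -24 * eps * (2 * s6^2 - s6) / r
}

#' Wall-bead lattice for the bead-built cylinder barrel
#'
#' Rings of wall beads on the cylinder of radius \eqn{D/2 + \sigma_{13}}
#' (matching the smooth wall's contact convention), with approximately equal
#' axial and azimuthal spacing `geometry$bead_spacing`.
#'
#' @param geometry a [cylinder_geometry()].
#' @param sigma13 monomer-wall interaction length.
#' @return Matrix of bead coordinates (n x 3).
#' @export
wall_beads <- function(geometry, sigma13 = 1) {
  rad <- geometry$diameter / 2 + sigma13
  sp <- geometry$bead_spacing
  n_ring <- max(6L, ceiling(2 * pi * rad / sp))
  n_z <- max(1L, round(geometry$length / sp))
  dz <- geometry$length / n_z
  ang <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
  out <- lapply(seq_len(n_z), function(k) {
    # offset alternate rings by half a spacing for a less grooved surface
    a <- ang + (k %% 2) * pi / n_ring
    cbind(rad * cos(a), rad * sin(a), (k - 0.5) * dz)
  })
  do.call(rbind, out)
}

# ---------------------------------------------------------------------------

#' Brute-force forces and energy breakdown (reference oracle)
#'
#' Plain O(n^2) summation of all WCA pairs (minimum image in the periodic
#' direction), all FENE ring bonds and all wall terms, written independently
#' of the cell-list production path so the two can be checked against each
#' other.  Intended for small fixtures.
#'
#' @param state a [particle_state()].
#' @param spec a [system_spec()].
#' @param topology a [ring_topology()]; defaults to the ring implied by `spec`.
#' @return `list(forces =, energy = list(pair, bond, wall, total))`.
#' @export
brute_force_forces <- function(state, spec,
                               topology = ring_topology(spec$n_monomers)) {
  p <- state$positions
  sp <- state$species
  n <- nrow(p)
  g <- spec$geometry
  tab <- spec$interactions
  forces <- matrix(0, n, 3)
  e_pair <- 0
  if (g$wall_model == "beads") {
    wb <- wall_beads(g, tab$sigma[1, 3])
    p <- rbind(p, wb)
    sp <- c(sp, rep(3L, nrow(wb)))
  }
  ntot <- nrow(p)
  for (i in seq_len(ntot - 1)) {
    for (j in (i + 1):ntot) {
      if (sp[i] == 3L && sp[j] == 3L) next
      dr <- p[i, ] - p[j, ]
      if (g$mode == "periodic") dr[3] <- dr[3] - g$length * round(dr[3] / g$length)
      r <- sqrt(sum(dr^2))
      sig <- tab$sigma[sp[i], sp[j]]
      if (r < 2^(1 / 6) * sig) {
        e_pair <- e_pair + wca_scalar(r, sig, tab$epsilon[sp[i], sp[j]])
        f <- -wca_dudr(r, sig, tab$epsilon[sp[i], sp[j]]) * dr / r
        if (i <= n) forces[i, ] <- forces[i, ] + f
        if (j <= n) forces[j, ] <- forces[j, ] - f
      }
    }
  }
  e_bond <- 0
  for (k in seq_len(nrow(topology$bonds))) {
    i <- topology$bonds[k, 1]; j <- topology$bonds[k, 2]
    dr <- state$positions[i, ] - state$positions[j, ]
    if (g$mode == "periodic") dr[3] <- dr[3] - g$length * round(dr[3] / g$length)
    r <- sqrt(sum(dr^2))
    if (r >= spec$bonds$r0) stop_overstretch(r, spec$bonds$r0)
    e_bond <- e_bond + fene_energy(r, spec$bonds)
    f <- fene_force(dr, spec$bonds)
    forces[i, ] <- forces[i, ] + f
    forces[j, ] <- forces[j, ] - f
  }
  e_wall <- 0
  smooth_geo <- g
  if (g$wall_model == "beads") {
    # barrel handled via explicit bead pairs above; only caps remain analytic
    smooth_geo$wall_model <- "smooth"
  }
  for (i in seq_len(n)) {
    if (state$species[i] == 3L) next
    if (g$wall_model == "beads") {
      if (g$mode == "capped") {
        wi <- cap_only_interaction(state$positions[i, ], state$species[i], g, tab)
        e_wall <- e_wall + wi$energy
        forces[i, ] <- forces[i, ] + wi$force
      }
    } else {
      wi <- wall_interaction(state$positions[i, ], state$species[i], g, tab)
      e_wall <- e_wall + wi$energy
      forces[i, ] <- forces[i, ] + wi$force
    }
  }
  list(forces = forces,
       energy = list(pair = e_pair, bond = e_bond, wall = e_wall,
                     total = e_pair + e_bond + e_wall))
}

cap_only_interaction <- function(position, species, geometry, table) {
  s <- species_index(species)
  sw <- table$sigma[s, 3]
  cutoff <- 2^(1 / 6) * sw
  energy <- 0; force <- c(0, 0, 0)
  hlo <- position[3] + sw
  hhi <- geometry$length - position[3] + sw
  if (hlo < cutoff) {
    energy <- energy + wca_scalar(hlo, sw, table$epsilon[s, 3])
    force[3] <- force[3] - wca_dudr(hlo, sw, table$epsilon[s, 3])
  }
  if (hhi < cutoff) {
    energy <- energy + wca_scalar(hhi, sw, table$epsilon[s, 3])
    force[3] <- force[3] + wca_dudr(hhi, sw, table$epsilon[s, 3])
  }
  list(energy = energy, force = force)
}

#' Cell-list forces (production path)
#'
#' Computes the same force field and energy breakdown as
#' [brute_force_forces()] through the compiled cell-list kernels; agreement
#' between the two paths is part of the test suite.
#'
#' @inheritParams brute_force_forces
#' @export
compute_forces <- function(state, spec,
                           topology = ring_topology(spec$n_monomers)) {
  eng <- engine_inputs(state, spec, topology)
  res <- .cpp_compute_forces(eng$positions, eng$species0, eng$par)
  if (!res$ok) stop_integration(res$message)
  n <- nrow(state$positions)
  list(forces = res$forces[seq_len(n), , drop = FALSE], energy = res$energy)
}

# Pack state + spec into the flat argument list the compiled kernels expect.
# Wall beads (beads wall model) are appended as static species-3 particles.
engine_inputs <- function(state, spec, topology = NULL) {
  g <- spec$geometry
  tab <- spec$interactions
  pos <- state$positions
  vel <- state$velocities
  sp <- state$species
  img <- state$images
  n_mobile <- nrow(pos)
  if (g$wall_model == "beads") {
    wb <- wall_beads(g, tab$sigma[1, 3])
    pos <- rbind(pos, wb)
    vel <- rbind(vel, matrix(0, nrow(wb), 3))
    sp <- c(sp, rep(3L, nrow(wb)))
    img <- c(img, integer(nrow(wb)))
  }
  n_ring <- if (is.null(topology) || nrow(topology$bonds) > 0)
    spec$n_monomers else 0L
  par <- list(
    n_mono = spec$n_monomers,
    n_ring = n_ring,
    n_mobile = n_mobile,
    n = nrow(pos),
    sigma = tab$sigma,
    epsilon = tab$epsilon,
    fene_k = spec$bonds$k,
    fene_r0 = spec$bonds$r0,
    dt = spec$dynamics$dt,
    gamma = spec$dynamics$gamma,
    kT = spec$dynamics$temperature,
    mass = unname(spec$dynamics$mass),
    radius = g$diameter / 2,
    length = g$length,
    periodic = g$mode == "periodic",
    smooth_wall = g$wall_model == "smooth",
    wall_sigma = c(tab$sigma[1, 3], tab$sigma[2, 3]),
    wall_epsilon = c(tab$epsilon[1, 3], tab$epsilon[2, 3]))
  list(positions = pos, velocities = vel, species0 = sp - 1L, images = img,
       par = par)
}
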