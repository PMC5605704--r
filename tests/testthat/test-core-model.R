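test_that("interaction table obeys symmetry and the mixing rule", {
  tab <- interaction_table(eps13 = 2, a = 1, a_c = 0.3)
  expect_identical(tab$sigma, t(tab$sigma))
  expect_identical(tab$epsilon, t(tab$epsilon))
  expect_equal(tab$sigma[1, 2], (1 + 0.3) / 2)
  expect_equal(tab$sigma[2, 3], (0.3 + 1) / 2)
  expect_equal(tab$epsilon[1, 3], 2)
  expect_equal(tab$epsilon[1, 1], 1)
})

test_that("WCA energy matches the closed form and is exactly zero at the cutoff", {
  tab <- interaction_table()
  rc <- 2^(1 / 6)
  expect_identical(wca_energy(rc, 1, 1, tab), 0)
  expect_identical(wca_energy(5, 1, 1, tab), 0)
  expect_equal(wca_energy(1, 1, 1, tab), 1)          # 4(1 - 1 + 1/4) = eps
  # frozen one-line formula evaluation at r = 0.9 sigma
  expect_equal(wca_energy(0.9, 1, 1, tab), 7.63611895325292, tolerance = 1e-12)
  # crowder pair scales with sigma22 = 0.3
  expect_equal(wca_energy(0.3, 2, 2, tab), 1)
  expect_error(wca_energy(0, 1, 1, tab), "positive")
})

test_that("WCA force is repulsive, zero beyond cutoff, and matches finite differences", {
  tab <- interaction_table(eps13 = 2.5)
  rc <- 2^(1 / 6)
  expect_identical(wca_force(c(rc, 0, 0), 1, 1, tab), c(0, 0, 0))
  f <- wca_force(c(0.95, 0, 0), 1, 1, tab)
  expect_gt(f[1], 0)                                  # points away from partner
  expect_equal(f[2:3], c(0, 0))
  expect_error(wca_force(c(0, 0, 0), 1, 1, tab), "zero-length")
  set.seed(42)
  for (k in 1:200) {
    cfg <- random_pair_config(k)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    sig <- tab$sigma[cfg$i, cfg$j]
    rvec <- cfg$r * sig * dir
    f <- wca_force(rvec, cfg$i, cfg$j, tab)
    g <- -numeric_gradient(function(x)
      wca_energy(sqrt(sum(x^2)), cfg$i, cfg$j, tab), rvec, h = 1e-6 * sig)
    expect_equal(f, g, tolerance = 1e-6)
  }
})

test_that("FENE energy is zero at zero extension, divergent toward r0, and overstretch errors", {
  b <- bond_params()
  expect_equal(fene_energy(0, b), 0)
  expect_gt(fene_energy(1.49, b), fene_energy(1.0, b))
  expect_gt(fene_energy(1.4999, b), 80)               # log singularity
  expect_error(fene_energy(1.5, b), class = "crowdring_overstretch")
  expect_error(fene_energy(2, b), class = "crowdring_overstretch")
  # frozen direct evaluation at r = 0.75 r0
  expect_equal(fene_energy(0.75 * 1.5, b), 27.9004018449758, tolerance = 1e-12)
})

test_that("FENE force is attractive, Hookean at small r, and matches finite differences", {
  b <- bond_params()
  expect_identical(fene_force(c(0, 0, 0), b), c(0, 0, 0))
  f <- fene_force(c(1e-4, 0, 0), b)
  expect_equal(f[1], -30 * 1e-4, tolerance = 1e-6)    # k r toward partner
  rvec <- c(0.8, 0.7, 0.6) / sqrt(0.8^2 + 0.7^2 + 0.6^2) * 0.9 * 1.5
  f <- fene_force(rvec, b)
  g <- -numeric_gradient(function(x) fene_energy(sqrt(sum(x^2)), b), rvec)
  expect_equal(f, g, tolerance = 1e-6)
  expect_error(fene_force(c(1.5, 0, 0), b), class = "crowdring_overstretch")
})

test_that("smooth wall: inactive on the axis, eps at contact, purely radial inward force", {
  tab <- interaction_table(eps13 = 1)
  geo <- cylinder_geometry(5, 20)
  on_axis <- wall_interaction(c(0, 0, 10), 1, geo, tab)
  expect_identical(on_axis$energy, 0)
  expect_identical(on_axis$force, c(0, 0, 0))
  # center on the nominal surface rho = D/2: effective gap sigma13, energy eps
  at_wall <- wall_interaction(c(2.5, 0, 10), 1, geo, tab)
  expect_equal(at_wall$energy, 1)
  expect_lt(at_wall$force[1], 0)                      # inward
  expect_equal(at_wall$force[2:3], c(0, 0))
  # crowder at effective gap 0.6a, sigma23 = 0.65: frozen direct evaluation
  rho <- 2.5 + 0.65 - 0.6
  cr <- wall_interaction(c(0, rho, 10), 2, geo, tab)
  expect_equal(cr$energy, 4.98618688920805, tolerance = 1e-12)
  # force magnitude matches a finite difference in rho
  h <- 1e-6
  e1 <- wall_interaction(c(0, rho + h, 10), 2, geo, tab)$energy
  e2 <- wall_interaction(c(0, rho - h, 10), 2, geo, tab)$energy
  expect_equal(cr$force[2], -(e1 - e2) / (2 * h), tolerance = 1e-5)
})

test_that("capped walls repel along the axis with the same WCA law", {
  tab <- interaction_table()
  geo <- cylinder_geometry(5, 10, mode = "capped")
  low <- wall_interaction(c(0, 0, 0), 1, geo, tab)    # center on the cap plane
  expect_equal(low$energy, 1)
  expect_gt(low$force[3], 0)
  high <- wall_interaction(c(0, 0, 10), 1, geo, tab)
  expect_lt(high$force[3], 0)
  mid <- wall_interaction(c(0, 0, 5), 1, geo, tab)
  expect_identical(mid$energy, 0)
})

test_that("bead-built wall repels through the pair path", {
  tab <- interaction_table()
  geo <- cylinder_geometry(5, 6, wall_model = "beads", bead_spacing = 0.5)
  wb <- wall_beads(geo, 1)
  expect_true(all(abs(sqrt(rowSums(wb[, 1:2]^2)) - 3.5) < 1e-9))
  near <- wall_interaction(c(2.5, 0, 3), 1, geo, tab)
  expect_gt(near$energy, 0)
  expect_lt(sum(near$force[1:2] * c(2.5, 0)) / 2.5, 0)  # net inward
  far <- wall_interaction(c(0, 0, 3), 1, geo, tab)
  expect_identical(far$energy, 0)
})

test_that("cell-list forces reproduce the brute-force oracle on all fixtures", {
  for (name in c("dimer", "triangle-ring", "ring20", "ring20+crowders")) {
    fx <- make_fixture(name)
    bf <- brute_force_forces(fx$state, fx$spec, fx$topology)
    cf <- compute_forces(fx$state, fx$spec, fx$topology)
    expect_lt(max(abs(bf$forces - cf$forces)), 1e-10)
    expect_equal(cf$energy$pair, bf$energy$pair, tolerance = 1e-12)
    expect_equal(cf$energy$bond, bf$energy$bond, tolerance = 1e-12)
    expect_equal(cf$energy$wall, bf$energy$wall, tolerance = 1e-12)
  }
})

test_that("pair forces obey Newton's third law and a lone particle feels nothing", {
  fx <- make_fixture("dimer")
  bf <- brute_force_forces(fx$state, fx$spec, fx$topology)
  expect_equal(bf$forces[1, ], -bf$forces[2, ])
  expect_gt(sum(bf$forces[1, ]^2), 0)                 # contact at sigma is repulsive
  # ring20 sits well inside the wall: wall terms vanish, so total momentum is conserved
  fx2 <- make_fixture("ring20")
  bf2 <- brute_force_forces(fx2$state, fx2$spec, fx2$topology)
  expect_equal(bf2$energy$wall, 0)
  expect_lt(max(abs(colSums(bf2$forces))), 1e-10)
  # single off-wall particle
  one <- particle_state(matrix(c(0, 0, 5), 1), species = 1L)
  topo0 <- make_fixture("dimer")$topology
  spec1 <- fx$spec; spec1$n_monomers <- 1L
  bf1 <- brute_force_forces(one, spec1, topo0)
  expect_identical(bf1$forces, matrix(0, 1, 3))
})

test_that("energies are invariant under rotation about the cylinder axis", {
  fx <- make_fixture("ring20+crowders")
  e0 <- compute_forces(fx$state, fx$spec, fx$topology)$energy$total
  for (ang in c(0.3, 1.7, 4.4)) {
    rot <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
    st <- fx$state
    st$positions <- fx$state$positions %*% rot
    e1 <- compute_forces(st, fx$spec, fx$topology)$energy$total
    expect_equal(e1, e0, tolerance = 1e-10)
  }
})

test_that("forces match the numeric gradient of the total brute energy", {
  fx <- make_fixture("ring20+crowders")
  st <- fx$state
  bf <- brute_force_forces(st, fx$spec, fx$topology)
  for (i in c(1L, 5L, 25L, 60L)) {                    # monomers and crowders
    g <- numeric_gradient(function(x) {
      s2 <- st
      s2$positions[i, ] <- x
      brute_force_forces(s2, fx$spec, fx$topology)$energy$total
    }, st$positions[i, ], h = 1e-6)
    expect_equal(bf$forces[i, ], -g, tolerance = 1e-5)
  }
})

test_that("pairs straddling the periodic boundary feel minimum-image forces", {
  fx <- make_fixture("dimer")
  spec <- fx$spec
  L <- spec$geometry$length
  st <- fx$state
  st$positions <- rbind(c(0, 0, 0.3), c(0, 0, L - 0.7))  # min-image distance 1
  bf <- brute_force_forces(st, spec, fx$topology)
  cf <- compute_forces(st, spec, fx$topology)
  st2 <- fx$state
  st2$positions <- rbind(c(0, 0, 5.3), c(0, 0, 4.3))     # unwrapped equivalent
  bf2 <- brute_force_forces(st2, spec, fx$topology)
  expect_equal(abs(bf$forces[1, 3]), abs(bf2$forces[1, 3]), tolerance = 1e-12)
  expect_lt(max(abs(bf$forces - cf$forces)), 1e-10)
})
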