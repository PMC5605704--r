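test_that("helical ring construction satisfies its geometric postconditions", {
  for (cfg in list(list(n = 3L, d = 5, l = 12), list(n = 20L, d = 5, l = 12),
                   list(n = 135L, d = 5, l = 78), list(n = 135L, d = 3, l = 120))) {
    geo <- cylinder_geometry(cfg$d, cfg$l)
    p <- build_ring(cfg$n, geo)
    expect_equal(nrow(p), cfg$n)
    bl <- sqrt(rowSums((p - p[c(2:cfg$n, 1), ])^2))
    expect_true(all(bl >= 0.9 & bl <= 1.1))           # includes the closing bond
    dm <- as.matrix(dist(p)); diag(dm) <- Inf
    expect_gte(min(dm), 0.85 - 1e-9)
    expect_true(all(sqrt(rowSums(p[, 1:2]^2)) <= cfg$d / 2))
  }
})

test_that("ring construction is deterministic and fails in infeasible geometry", {
  geo <- cylinder_geometry(5, 40)
  expect_identical(build_ring(135, geo), build_ring(135, geo))
  # a short capped tube cannot hold the coil
  expect_error(build_ring(135, cylinder_geometry(2.2, 6, mode = "capped")),
               "helical|feasible|narrow|short")
  # N = 3 degenerates to an equilateral triangle
  tri <- build_ring(3, geo)
  expect_equal(dist(tri)[1:3], rep(1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("crowder_count implements the nominal-volume formula", {
  geo <- cylinder_geometry(5, 78)
  expect_identical(crowder_count(0, geo, 0.3), 0L)
  # frozen hand arithmetic: round(0.3 * pi * 2.5^2 * 78 / (pi/6 * 0.027))
  expect_identical(crowder_count(0.3, geo, 0.3), 32500L)
  # linear in L up to rounding, monotone in phi
  n1 <- crowder_count(0.12, geo, 0.3)
  n2 <- crowder_count(0.12, cylinder_geometry(5, 156), 0.3)
  expect_lte(abs(n2 - 2 * n1), 1L)
  phis <- seq(0, 0.4, by = 0.02)
  counts <- vapply(phis, crowder_count, integer(1), geometry = geo, a_c = 0.3)
  expect_true(all(diff(counts) >= 0))
})

test_that("crowder placement is uniform over the cross-section at low density", {
  geo <- cylinder_geometry(5, 20)
  expect_identical(nrow(place_crowders(0, geo)), 0L)
  draws <- t(vapply(1:5000, function(k) place_crowders(1, geo, seed = k)[1, ],
                    numeric(3)))
  r2 <- rowSums(draws[, 1:2]^2) / 2.5^2      # uniform disc: r^2 ~ U(0,1)
  counts <- tabulate(findInterval(r2, seq(0, 1, length.out = 21),
                                  rightmost.closed = TRUE), nbins = 20)
  chi <- sum((counts - 250)^2 / 250)
  expect_gt(stats::pchisq(chi, df = 19, lower.tail = FALSE), 0.01)
  # z uniform as well
  cz <- tabulate(findInterval(draws[, 3] / 20, seq(0, 1, length.out = 21),
                              rightmost.closed = TRUE), nbins = 20)
  expect_gt(stats::pchisq(sum((cz - 250)^2 / 250), df = 19,
                          lower.tail = FALSE), 0.01)
})

test_that("placed crowders never overlap existing particles beyond 0.9 contact", {
  geo <- cylinder_geometry(5, 10)
  ring <- build_ring(20, geo)
  cr <- place_crowders(800, geo, existing = ring, existing_contact = 0.65,
                       a_c = 0.3, seed = 9)
  expect_equal(nrow(cr), 800)
  dmin <- min(dist(cr))
  expect_gte(dmin, 0.9 * 0.3 - 1e-12)
  cross <- sqrt(outer(rowSums(ring^2), rowSums(cr^2), "+") -
                2 * ring %*% t(cr))
  expect_gte(min(cross), 0.9 * 0.65 - 1e-9)
})

test_that("impossible packings raise a packing error naming the achieved count", {
  geo <- cylinder_geometry(5, 2)
  err <- tryCatch(place_crowders(5000, geo, a_c = 0.9, seed = 1,
                                 max_attempts = 20),
                  error = function(e) e)
  expect_s3_class(err, "crowdring_packing_error")
  expect_match(conditionMessage(err), "placed [0-9]+ of 5000")
})

test_that("build_system assembles a valid state at zero and moderate crowding", {
  spec0 <- system_spec(n_monomers = 20, phi_c = 0,
                       geometry = cylinder_geometry(5, 12), seed = 2)
  sys0 <- build_system(spec0)
  expect_identical(sum(sys0$state$species == 2L), 0L)
  expect_true(validate_state(sys0$state, spec0, sys0$topology))
  spec1 <- system_spec(n_monomers = 20, phi_c = 0.1,
                       geometry = cylinder_geometry(5, 12), seed = 2)
  sys1 <- build_system(spec1)
  expect_identical(sum(sys1$state$species == 2L),
                   crowder_count(0.1, spec1$geometry, 0.3))
  expect_true(validate_state(sys1$state, spec1, sys1$topology))
  # deterministic reconstruction
  sys1b <- build_system(spec1)
  expect_identical(sys1$state$positions, sys1b$state$positions)
})

test_that("high-density crowding is reached through the inflation protocol", {
  spec <- system_spec(n_monomers = 20, phi_c = 0.28,
                      geometry = cylinder_geometry(5, 6), seed = 4)
  sys <- build_system(spec)
  n_c <- crowder_count(0.28, spec$geometry, 0.3)
  expect_identical(sum(sys$state$species == 2L), n_c)
  expect_true(validate_state(sys$state, spec, sys$topology))
  # full-size crowders: no deep overlaps after inflation
  cr <- sys$state$positions[sys$state$species == 2L, ]
  expect_gte(min(dist(cr)), 0.8 * 0.3)
})

test_that("capped build keeps every bead between the caps", {
  geo <- cylinder_geometry(3, 26, mode = "capped")
  spec <- system_spec(n_monomers = 135, phi_c = 0, geometry = geo, seed = 1)
  sys <- build_system(spec)
  z <- sys$state$positions[, 3]
  expect_true(all(z > 0 & z < 26))
  expect_true(validate_state(sys$state, spec, sys$topology))
})

test_that("fixtures have their documented shapes", {
  dm <- make_fixture("dimer")
  expect_identical(nrow(dm$state$positions), 2L)
  expect_equal(dist(dm$state$positions)[1], 1, ignore_attr = TRUE)
  tri <- make_fixture("triangle-ring")
  expect_identical(nrow(tri$topology$bonds), 3L)
  expect_true(all(tabulate(tri$topology$bonds) == 2L))  # degree 2 everywhere
  r20 <- make_fixture("ring20+crowders")
  expect_identical(sum(r20$state$species == 2L), 50L)
  expect_error(make_fixture("no-such-fixture"), "unknown fixture")
})

test_that("arm pairing excludes the split beads and covers floor(N/2) - 1 pairs", {
  topo <- ring_topology(135)
  expect_identical(nrow(topo$arm_pairs), 66L)
  expect_false(any(topo$split %in% topo$arm_pairs))
  expect_identical(anyDuplicated(as.vector(topo$arm_pairs)), 0L)
  expect_true(all(rowSums(topo$arm_pairs) == 137L))   # i+1 pairs N-i+1
  topo8 <- ring_topology(8)
  expect_identical(nrow(topo8$arm_pairs), 3L)
})
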