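test_that("free flight: with no forces and gamma = 0 positions advance by v dt", {
  fx <- make_fixture("dimer")
  st <- fx$state
  st$positions <- rbind(c(0, 0, 2), c(0, 0, 8))       # far apart: no forces
  st$velocities <- rbind(c(0.5, -0.25, 1), c(0, 0.75, -1))
  spec <- fx$spec
  spec$dynamics$gamma <- 0
  out <- langevin_step(st, spec, topology = fx$topology)
  expect_equal(out$positions, st$positions + 0.002 * st$velocities,
               tolerance = 1e-14)
  expect_equal(out$velocities, st$velocities, tolerance = 1e-14)
})

test_that("trajectories are bit-reproducible from (state, spec, seed)", {
  fx <- make_fixture("ring20+crowders")
  t1 <- integrate_dynamics(fx$state, fx$spec, n_steps = 2000,
                           sample_stride = 500, seed = 7)
  t2 <- integrate_dynamics(fx$state, fx$spec, n_steps = 2000,
                           sample_stride = 500, seed = 7)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$final_state$velocities, t2$final_state$velocities)
  t3 <- integrate_dynamics(fx$state, fx$spec, n_steps = 2000,
                           sample_stride = 500, seed = 8)
  expect_false(identical(t1$final_state$positions, t3$final_state$positions))
})

test_that("NVE limit: energy drift below 1e-3 relative over 1e4 steps", {
  fx <- make_fixture("ring20")
  spec <- fx$spec
  spec$dynamics$gamma <- 0
  traj <- integrate_dynamics(fx$state, spec, n_steps = 1e4, sample_stride = 50)
  n <- nrow(fx$state$positions)
  total <- traj$potential_energy + 1.5 * n * traj$kinetic_temperature
  expect_lt((max(total) - min(total)) / abs(mean(total)), 1e-3)
})

test_that("thermostat holds the kinetic temperature within 2 percent of target", {
  fx <- make_fixture("ring20")
  traj <- integrate_dynamics(fx$state, fx$spec, n_steps = 2e5,
                             sample_stride = 100, seed = 12)
  kt <- traj$kinetic_temperature
  kt <- kt[-seq_len(length(kt) %/% 5)]                # discard equilibration
  expect_lt(abs(mean(kt) - 1), 0.02)
})

test_that("periodic wrapping updates image counters and round-trips", {
  geo <- cylinder_geometry(5, 10)
  st <- particle_state(rbind(c(0, 0, 10.3), c(0, 0, -0.1), c(0, 0, 4)),
                       species = c(1L, 1L, 1L))
  w <- apply_periodic(st, geo)
  expect_equal(w$positions[, 3], c(0.3, 9.9, 4))
  expect_identical(w$images, c(1L, -1L, 0L))
  # unwrapped coordinates are recovered exactly
  expect_equal(w$positions[, 3] + w$images * 10, st$positions[, 3])
  set.seed(1)
  z <- runif(50, -30, 30)
  st2 <- particle_state(cbind(0, 0, z), species = rep(1L, 50))
  w2 <- apply_periodic(st2, geo)
  expect_true(all(w2$positions[, 3] >= 0 & w2$positions[, 3] < 10))
  expect_equal(w2$positions[, 3] + w2$images * 10, z)
  expect_error(apply_periodic(st, cylinder_geometry(5, 10, mode = "capped")),
               "capped")
})

test_that("kinetic temperature follows the equipartition convention", {
  st <- particle_state(matrix(0, 10, 3), matrix(0, 10, 3), rep(1L, 10))
  expect_identical(kinetic_temperature(st), 0)
  set.seed(3)
  v <- matrix(rnorm(30), 10, 3)
  st$velocities <- v
  t1 <- kinetic_temperature(st)
  st$velocities <- 2 * v
  expect_equal(kinetic_temperature(st), 4 * t1)
  # Maxwell-Boltzmann draws at k_BT = eps average to 1
  spec <- system_spec(n_monomers = 20, phi_c = 0.2,
                      geometry = cylinder_geometry(5, 15), seed = 6)
  sys <- build_system(spec)
  expect_equal(kinetic_temperature(sys$state, spec), 1,
               tolerance = 3 * sqrt(2 / (3 * nrow(sys$state$positions))))
})

test_that("integration keeps bonds and containment valid over a long sweep", {
  fx <- make_fixture("ring20")
  traj <- integrate_dynamics(fx$state, fx$spec, n_steps = 5e4,
                             sample_stride = 250, seed = 21)
  expect_true(check_frames_valid(traj, fx$spec, fx$topology))
})

test_that("zero steps yields a single-frame trajectory of the input state", {
  fx <- make_fixture("ring20")
  traj <- integrate_dynamics(fx$state, fx$spec, n_steps = 0)
  expect_identical(length(traj$frames), 1L)
  expect_equal(traj$frames[[1]], unname(fx$state$positions))
  expect_identical(traj$steps, 0L)
})

test_that("blow-ups raise an integration failure naming the step, with partial frames", {
  fx <- make_fixture("ring20")
  st <- fx$state
  st$velocities[1, ] <- c(0, 0, 4000)                 # guarantees overstretch
  err <- tryCatch(
    integrate_dynamics(st, fx$spec, n_steps = 1000, sample_stride = 10),
    error = function(e) e)
  expect_s3_class(err, "crowdring_integration_failure")
  expect_match(conditionMessage(err), "step [0-9]+")
  expect_s3_class(err$partial, "trajectory")
  expect_gte(length(err$partial$frames), 1L)
})
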