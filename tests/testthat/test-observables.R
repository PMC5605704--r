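test_that("longitudinal span unwraps across the periodic boundary", {
  geo <- cylinder_geometry(5, 12)
  topo <- ring_topology(20)
  ring <- build_ring(20, geo)
  expect_equal(longitudinal_span(ring, topo, geo),
               max(ring[, 3]) - min(ring[, 3]))
  # rigid translation leaves R unchanged; wrapping across the boundary too
  shifted <- ring
  shifted[, 3] <- shifted[, 3] + 7.5
  wrapped <- shifted
  wrapped[, 3] <- wrapped[, 3] %% 12
  expect_equal(longitudinal_span(shifted, topo, geo),
               longitudinal_span(ring, topo, geo), tolerance = 1e-12)
  expect_equal(longitudinal_span(wrapped, topo, geo),
               longitudinal_span(ring, topo, geo), tolerance = 1e-12)
  # a flat ring has zero span
  flat <- ring; flat[, 3] <- 3
  expect_identical(longitudinal_span(flat, topo, geo), 0)
})

test_that("a ring wound around the periodic direction is reported, not silently unwrapped", {
  geo <- cylinder_geometry(5, 6)
  topo <- ring_topology(12)
  # helical path that gains a full box length over the ring: winding number 1
  z <- (seq_len(12) - 1) * 0.5
  ang <- 2 * pi * (seq_len(12) - 1) / 12
  frame <- cbind(cos(ang), sin(ang), z %% 6)
  expect_error(longitudinal_span(frame, topo, geo), "self-wrap|winds")
})

test_that("mean squared radial position is 0 on the axis, 1 at the wall, 0.5 for uniform", {
  geo <- cylinder_geometry(5, 10)
  onaxis <- cbind(0, 0, seq(0, 9, length.out = 30))
  expect_identical(mean_sq_radial(onaxis, geo), 0)
  ang <- seq(0, 2 * pi, length.out = 30)
  atwall <- cbind(2.5 * cos(ang), 2.5 * sin(ang), 5)
  expect_equal(mean_sq_radial(atwall, geo), 1)
  set.seed(11)
  r <- 2.5 * sqrt(runif(1e5)); th <- 2 * pi * runif(1e5)
  unif <- cbind(r * cos(th), r * sin(th), 0)
  expect_equal(mean_sq_radial(unif, geo), 0.5, tolerance = 0.005)
})

test_that("arm correlation hits its limits and vanishes for independent angles", {
  geo <- cylinder_geometry(5, 10)
  topo <- ring_topology(20)
  ap <- topo$arm_pairs
  frame <- matrix(0, 20, 3)
  # all pairs diametrically opposite at the wall
  frame[ap[, 1], 1] <- 2.5
  frame[ap[, 2], 1] <- -2.5
  expect_equal(arm_correlation(frame, topo, geo), -1)
  # all pairs coincident at the wall
  frame[ap[, 2], 1] <- 2.5
  expect_equal(arm_correlation(frame, topo, geo), 1)
  # independent uniform angles at fixed radius average to zero
  set.seed(5)
  vals <- vapply(1:2000, function(k) {
    th <- runif(20, 0, 2 * pi)
    f <- cbind(2.5 * cos(th), 2.5 * sin(th), 0)
    arm_correlation(f, topo, geo)
  }, numeric(1))
  expect_lt(abs(mean(vals)), 3 / sqrt(2000 * nrow(ap) / 2))
  expect_true(all(vals >= -1 & vals <= 1))
})

test_that("arm correlation is invariant under axis rotation and arm swap", {
  fx <- make_fixture("ring20")
  geo <- fx$spec$geometry
  frame <- fx$state$positions
  a0 <- arm_correlation(frame, fx$topology, geo)
  rot <- matrix(c(cos(1.1), sin(1.1), 0, -sin(1.1), cos(1.1), 0, 0, 0, 1), 3, 3)
  expect_equal(arm_correlation(frame %*% rot, fx$topology, geo), a0,
               tolerance = 1e-12)
  swapped <- fx$topology
  swapped$arm_pairs <- swapped$arm_pairs[, c(2, 1)]
  expect_equal(arm_correlation(frame, swapped, geo), a0, tolerance = 1e-12)
  m0 <- mean_sq_radial(frame, geo)
  shifted <- frame; shifted[, 3] <- shifted[, 3] + 4
  expect_equal(mean_sq_radial(shifted %*% rot, geo), m0, tolerance = 1e-12)
})

test_that("projected profile of uniform points matches the semicircle law", {
  geo <- cylinder_geometry(5, 10)
  set.seed(19)
  n <- 5e4
  r <- 2.5 * sqrt(runif(n)); th <- 2 * pi * runif(n)
  frames <- list(cbind(r * cos(th), r * sin(th), 5))
  prof <- projected_profile(frames, n_bins = 41, geometry = geo)
  # closed form: the projection of a uniform disc has density
  # (2/pi) sqrt(1 - x^2); compare bin-averaged values via its antiderivative
  cdf <- function(x) (x * sqrt(pmax(0, 1 - x^2)) + asin(pmin(1, pmax(-1, x)))) / pi + 0.5
  width <- prof$bin_hi - prof$bin_lo
  expected <- (cdf(prof$bin_hi) - cdf(prof$bin_lo)) / width
  n_samp <- 2 * n
  binom_noise <- sqrt(pmax(expected, 1e-3) / (n_samp * width))
  expect_lt(max(abs(prof$density - expected) / (3 * binom_noise + 1e-9)), 1)
  # unit integral and evenness
  expect_equal(sum(prof$density * diff(c(prof$bin_lo[1], prof$bin_hi))), 1,
               tolerance = 1e-9)
  asym <- max(abs(prof$density - rev(prof$density)))
  expect_lt(asym, 6 * max(binom_noise))
})

test_that("a thin shell projects onto two symmetric peaks", {
  geo <- cylinder_geometry(5, 10)
  set.seed(23)
  th <- 2 * pi * runif(4e4)
  frames <- list(cbind(2 * cos(th), 2 * sin(th), 1))   # rescaled radius 0.8
  prof <- projected_profile(frames, n_bins = 41, geometry = geo)
  pk <- prof$center[which.max(prof$density)]
  expect_gt(abs(pk), 0.7)
  expect_true(is_bimodal(prof))
  d0 <- prof$density[which.min(abs(prof$center))]
  expect_lt(d0, max(prof$density) / 2)
  expect_error(projected_profile(frames, n_bins = 3, geometry = geo),
               "at least 4")
})

test_that("state classification maps the canonical regimes and is total", {
  s <- function(m, a) list(mean_sq_r = m, arm_corr = a)
  expect_identical(classify_state(s(0.95, 0.0)), "iii")
  expect_identical(classify_state(s(0.5, 0.3)), "iv")
  expect_identical(classify_state(s(0.4, -0.1)), "i")
  expect_identical(classify_state(s(0.9, -0.35)), "ii")
  expect_identical(classify_state(s(0.4, 0.05)), "iii_prime")
  expect_error(classify_state(list(mean_sq_r = 0.5)), "arm_corr")
  # total and deterministic over the whole square
  grid <- expand.grid(m = seq(0, 1.1, by = 0.05), a = seq(-1, 1, by = 0.05))
  labs <- mapply(function(m, a) classify_state(s(m, a)), grid$m, grid$a)
  expect_true(all(labs %in% c("i", "ii", "iii", "iii_prime", "iv")))
  labs2 <- mapply(function(m, a) classify_state(s(m, a)), grid$m, grid$a)
  expect_identical(labs, labs2)
})

test_that("ensemble averaging reproduces hand-computed means and standard errors", {
  mk <- function(R, m, a) structure(
    list(R = R, mean_sq_r = m, arm_corr = a, R_over_R0 = NA_real_,
         r0 = NA_real_, se = c(R = 0, mean_sq_r = 0, arm_corr = 0),
         n_frames = 10, replicates = 1L, single_replicate = TRUE),
    class = "run_summary")
  one <- ensemble_average(list(mk(26, 0.4, -0.1)))
  expect_identical(one$replicates, 1L)
  expect_true(one$single_replicate)
  expect_identical(unname(one$se["R"]), 0)
  same <- ensemble_average(list(mk(26, 0.4, -0.1), mk(26, 0.4, -0.1)))
  expect_identical(unname(same$se["R"]), 0)
  mix <- ensemble_average(list(mk(24, 0.3, -0.2), mk(28, 0.5, 0.0)))
  expect_equal(mix$R, 26)
  expect_equal(unname(mix$se["R"]), sd(c(24, 28)) / sqrt(2))
  expect_equal(mix$mean_sq_r, 0.4)
  expect_equal(unname(mix$se["arm_corr"]), sd(c(-0.2, 0)) / sqrt(2))
})

test_that("frame summaries discard the requested equilibration fraction", {
  obs <- data.frame(step = 1:10, R = 1:10, mean_sq_r = rep(0.5, 10),
                    arm_corr = rep(0, 10))
  s <- summarize_run(obs, discard_fraction = 0.2, r0 = 2)
  expect_equal(s$R, mean(3:10))
  expect_equal(s$R_over_R0, mean(3:10) / 2)
  s0 <- summarize_run(obs, discard_fraction = 0, r0 = NULL)
  expect_equal(s0$R, 5.5)
})
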