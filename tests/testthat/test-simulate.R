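test_that("calcium protocols produce the configured concentrations", {
  con <- calcium_protocol("constant", constant_ca = 0.4)
  expect_equal(protocol_ca(con, c(0, 1, 2)), rep(0.4, 3))
  tr <- calcium_protocol("transient", diastolic = 0.1, peak = 1,
                         tau_rise = 0.02, tau_decay = 0.15, stim_time = 1)
  t <- seq(0, 3, by = 1e-4)
  ca <- protocol_ca(tr, t)
  expect_true(all(ca[t < 1] == 0.1))
  expect_equal(max(ca), 1, tolerance = 1e-6)
  expect_equal(ca[length(ca)], 0.1, tolerance = 1e-2)
  expect_true(all(ca >= 0.1 - 1e-12))
})

test_that("the integrator step guard rejects an oversized dt by name", {
  p <- model_parameters()
  expect_error(
    simulate_filament(p, calcium_protocol("constant", constant_ca = 100),
                      duration = 0.01, dt = 2e-5, n_trajectories = 1),
    "dt guard violated"
  )
})

test_that("trajectories are reproducible for a fixed seed and differ across seeds", {
  p <- model_parameters(n_units = 4L)
  prot <- calcium_protocol("constant", constant_ca = 1)
  a <- simulate_filament(p, prot, duration = 0.3, n_trajectories = 3, seed = 5)
  b <- simulate_filament(p, prot, duration = 0.3, n_trajectories = 3, seed = 5)
  c <- simulate_filament(p, prot, duration = 0.3, n_trajectories = 3, seed = 6)
  expect_identical(a$force, b$force)
  expect_false(identical(a$force, c$force))
})

test_that("force stays within [0, n_units] and the trace is flat without a stimulus", {
  p <- model_parameters()
  prot <- calcium_protocol("constant", constant_ca = 0.1)
  tr <- simulate_filament(p, prot, duration = 2, n_trajectories = 8, seed = 2)
  expect_true(all(tr$force >= 0 & tr$force <= p$n_units))
  # after the initial relaxation the diastolic trace has no trend
  late <- tr$force[tr$time > 0.5]
  half <- length(late) %/% 2
  expect_lt(abs(mean(late[1:half]) - mean(late[(half + 1):length(late)])), 0.25)
})

test_that("single-unit Monte-Carlo occupancy matches the exact stationary law", {
  p <- model_parameters(n_units = 1L)
  pi_exact <- stationary_distribution_single_unit(p, ca = 1)
  tr <- simulate_filament(p, calcium_protocol("constant", constant_ca = 1),
                          duration = 30, n_trajectories = 10, seed = 42,
                          occupancy_burnin = 2)
  tv <- 0.5 * sum(abs(attr(tr, "occupancy") - pi_exact))
  expect_lt(tv, 0.02)
})

test_that("wild-type filament force at pCa 9 is under 5% of the unit count", {
  p <- model_parameters()
  f <- steady_state_force(p, pca = 9, n_trajectories = 8, seed = 3)
  expect_lt(as.numeric(f) / p$n_units, 0.05)
})

test_that("ensemble standard error shrinks roughly as 1 / sqrt(n)", {
  p <- model_parameters()
  f <- steady_state_force(p, pca = 6, n_trajectories = 16, seed = 9,
                          duration = 2)
  tm <- attr(f, "traj_mean")
  expect_length(tm, 16)
  se8 <- sd(tm[1:8]) / sqrt(8)
  se16 <- sd(tm) / sqrt(16)
  # halving the sample roughly sqrt(2)-inflates the SE; allow wide slack
  expect_lt(se16, se8 * 1.5)
  expect_equal(attr(f, "se"), sd(tm) / sqrt(16))
})

test_that("twitch simulation averages repeats and keeps the baseline", {
  p <- model_parameters(n_units = 8L)
  prot <- calcium_protocol("transient", stim_time = 0.3)
  tw <- simulate_twitch(p, prot, duration = 1.2, n_trajectories = 12,
                        n_repeats = 2, seed = 4)
  expect_s3_class(tw, "filament_trajectory")
  expect_equal(attr(tw, "stim_time"), 0.3)
  expect_true(min(tw$time) < 0.3)  # pre-stimulus baseline present
  # a pinned "transient" at the diastolic level produces no twitch
  flatp <- calcium_protocol("transient", diastolic = 0.1, peak = 0.1,
                            stim_time = 0.3)
  flat <- simulate_twitch(p, flatp, duration = 1.2, n_trajectories = 12,
                          seed = 4)
  m <- twitch_metrics(flat)
  expect_lt(m$peak_force - m$diastolic_force, 0.6)
})

test_that("trajectory files round-trip through the text format", {
  p <- model_parameters(n_units = 2L)
  tr <- simulate_filament(p, calcium_protocol("constant", constant_ca = 0.5),
                          duration = 0.1, n_trajectories = 2, seed = 1)
  f <- tempfile(fileext = ".tsv")
  write_trajectory(tr, f)
  back <- read.delim(f)
  expect_equal(back$mean_force, tr$force, tolerance = 1e-9)
})
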