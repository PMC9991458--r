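# piecewise-linear twitch used as a hand-computable oracle
pw_trace <- function(dt = 1e-3) {
  t <- seq(0, 1, by = dt)
  f <- ifelse(t < 0.2, 0.1,
       ifelse(t < 0.35, 0.1 + 0.9 * (t - 0.2) / 0.15,
       ifelse(t < 0.85, 1.0 - 0.9 * (t - 0.35) / 0.5, 0.1)))
  data.frame(time = t, force = f)
}

test_that("force-to-velocity is linear and origin preserving", {
  expect_equal(force_to_velocity(0, 2.5), 0)
  expect_equal(force_to_velocity(c(1, 2), 2.5), c(2.5, 5))
  expect_error(force_to_velocity(1, 0), "viscosity_const")
})

test_that("noise-free Hill data are recovered exactly", {
  pca <- seq(9, 4, length.out = 10)
  for (par in list(c(1, 6.06, 0.44), c(1, 7.25, 0.69))) {
    v <- hill_velocity(pca, par[1], par[2], par[3])
    fit <- fit_hill(pca, v)
    expect_true(fit$converged)
    expect_equal(fit$vmax, par[1], tolerance = 1e-6)
    expect_equal(fit$pca50, par[2], tolerance = 1e-6)
    expect_equal(fit$n_hill, par[3], tolerance = 1e-6)
    # midpoint property: fitted curve at pca50 equals vmax / 2
    expect_equal(hill_velocity(fit$pca50, fit$vmax, fit$pca50, fit$n_hill),
                 fit$vmax / 2)
  }
})

test_that("Hill fits are unbiased under 5% noise against the grid oracle", {
  pca <- seq(9, 4, length.out = 8)
  truth <- c(vmax = 1, pca50 = 7.25, n_hill = 0.69)
  set.seed(314)
  ests <- t(replicate(50, {
    v <- hill_velocity(pca, truth[1], truth[2], truth[3]) *
      (1 + rnorm(length(pca), 0, 0.05))
    fit <- fit_hill(pca, v)
    grid <- thinfilament:::hill_grid_search(pca, v)
    c(fit$pca50, grid$pca50)
  }))
  se <- sd(ests[, 1]) / sqrt(nrow(ests))
  expect_lt(abs(mean(ests[, 1]) - truth[2]), 2 * se + 0.02)
  # nls refinement stays close to the dense grid-search oracle
  expect_lt(max(abs(ests[, 1] - ests[, 2])), 0.05)
})

test_that("rescaling velocities rescales vmax only", {
  pca <- seq(8.5, 4.5, length.out = 9)
  v <- hill_velocity(pca, 2, 6.5, 1.2)
  f1 <- fit_hill(pca, v)
  f2 <- fit_hill(pca, 10 * v)
  expect_equal(f2$vmax, 10 * f1$vmax, tolerance = 1e-6)
  expect_equal(f2$pca50, f1$pca50, tolerance = 1e-6)
  expect_equal(f2$n_hill, f1$n_hill, tolerance = 1e-6)
})

test_that("twitch metrics match the piecewise-linear oracle", {
  m <- twitch_metrics(pw_trace(), stimulus_time = 0.2)
  expect_equal(m$diastolic_force, 0.1, tolerance = 1e-6)
  expect_equal(m$peak_force, 1.0, tolerance = 1e-6)
  expect_equal(m$time_to_peak, 0.15, tolerance = 1e-3)
  expect_equal(m$rt50, 0.25, tolerance = 1e-3)
  expect_false(m$rt50_censored)
  # triangle areas above baseline: 0.5*0.9*0.15 + 0.5*0.9*0.5 = 0.2925
  expect_equal(m$fti, 0.2925, tolerance = 1e-3)
})

test_that("flat and shifted traces behave as expected", {
  t <- seq(0, 1, by = 1e-3)
  flat <- data.frame(time = t, force = rep(0.3, length(t)))
  m <- twitch_metrics(flat, stimulus_time = 0.2)
  expect_equal(m$peak_force, m$diastolic_force)
  expect_equal(m$fti, 0, tolerance = 1e-12)
  expect_true(m$rt50_censored)

  tr <- pw_trace()
  shifted <- data.frame(time = tr$time + 5, force = tr$force)
  m1 <- twitch_metrics(tr, 0.2)
  m2 <- twitch_metrics(shifted, 5.2)
  for (field in c("diastolic_force", "peak_force", "time_to_peak", "rt50", "fti")) {
    expect_equal(m2[[field]], m1[[field]], tolerance = 1e-9)
  }
})

test_that("metrics are stable under 2x resampling", {
  m1 <- twitch_metrics(pw_trace(1e-3), 0.2)
  m2 <- twitch_metrics(pw_trace(5e-4), 0.2)
  for (field in c("diastolic_force", "peak_force", "time_to_peak", "rt50", "fti")) {
    expect_lt(abs(m2[[field]] - m1[[field]]) / abs(m1[[field]]), 0.01)
  }
})

test_that("insufficient Hill data are rejected", {
  expect_error(fit_hill(c(7, 6, 5), c(1, 2, 3)), "4 distinct")
  expect_error(fit_hill(c(7, 6), c(1, 2, 3)), "length")
})
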