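test_that("zero-perturbation profile is constant at the baseline", {
  p <- generate_flexibility_profile(3, span = 142, amplitude = 0, noise_sd = 0)
  expect_s3_class(p, "flexibility_profile")
  expect_equal(nrow(p), 142)
  expect_equal(p$residue, 1:142)
  expect_true(all(p$delta == 3))
})

test_that("noise-free bump peaks at the center and decays to baseline", {
  p <- generate_flexibility_profile(3, span = 142, center = 108, width = 5,
                                    amplitude = 2, noise_sd = 0)
  expect_equal(p$delta[108], 5)
  far <- p$delta[abs(p$residue - 108) > 40]
  expect_true(all(abs(far - 3) < 1e-8))
  expect_equal(which.max(p$delta), 108L)
})

test_that("profile noise reproduces the generating SD", {
  n_rep <- 1000
  draws <- sapply(seq_len(n_rep), function(i) {
    generate_flexibility_profile(3, span = 20, amplitude = 0, noise_sd = 0.2,
                                 seed = 5000 + i)$delta
  })
  sds <- apply(draws, 1, sd)
  expect_true(all(abs(sds - 0.2) / 0.2 < 0.1))
})

test_that("invalid profile inputs are rejected with the offending field named", {
  expect_error(generate_flexibility_profile(-1, span = 142), "baseline_delta")
  expect_error(generate_flexibility_profile(3, span = 1), "span")
  expect_error(generate_flexibility_profile(3, span = 142, amplitude = -3.5),
               "amplitude")
  expect_error(flexibility_profile("wt", c(1, 3, 4), c(1, 1, 1)), "contiguous")
  expect_error(flexibility_profile("wt", 1:3, c(1, -1, 1)), "positive")
})

test_that("energy frame sampling matches requested moments at large n", {
  e <- sample_energy_frames(-5108.7, 280.9, n_frames = 500, seed = 3,
                            genotype = "wt", state = "B")
  expect_equal(e$n_frames, 500)
  expect_lt(abs(mean(e$values) + 5108.7), 50)
  e2 <- sample_energy_frames(-4426.2, 206.2, n_frames = 500, seed = 4,
                             genotype = "s215l", state = "C")
  expect_lt(abs(sd(e2$values) - 206.2) / 206.2, 0.15)
  # convergence: large-n moments within 3 standard errors
  big <- sample_energy_frames(-100, 10, n_frames = 1e4, seed = 5)
  expect_lt(abs(mean(big$values) + 100), 3 * 10 / sqrt(1e4))
  expect_lt(abs(sd(big$values) - 10), 3 * 10 / sqrt(2 * (1e4 - 1)))
})

test_that("degenerate SD yields constant frames; tiny ensembles are rejected", {
  e <- sample_energy_frames(0, 0, n_frames = 500, seed = 1)
  expect_true(all(e$values == 0))
  expect_error(sample_energy_frames(0, 1, n_frames = 1), "n_frames")
})

test_that("generators are deterministic under a fixed seed", {
  a <- generate_flexibility_profile(3, 50, amplitude = 1, noise_sd = 0.3, seed = 9)
  b <- generate_flexibility_profile(3, 50, amplitude = 1, noise_sd = 0.3, seed = 9)
  expect_identical(a, b)
  x <- sample_energy_frames(-10, 2, 100, seed = 12)
  y <- sample_energy_frames(-10, 2, 100, seed = 12)
  expect_identical(x$values, y$values)
})

test_that("profile and frame files round-trip through their text formats", {
  p <- generate_flexibility_profile(3, 30, amplitude = 1.5, noise_sd = 0.1,
                                    seed = 2, genotype = "s215l")
  f <- tempfile(fileext = ".tsv")
  write_flexibility_profile(p, f)
  p2 <- read_flexibility_profile(f)
  expect_equal(attr(p2, "genotype"), "s215l")
  expect_equal(p2$delta, p$delta, tolerance = 1e-10)

  e <- sample_energy_frames(-50, 5, 40, seed = 8, genotype = "wt", state = "C")
  g <- tempfile()
  write_energy_frames(e, g)
  e2 <- read_energy_frames(g)
  expect_equal(e2$state, "C")
  expect_equal(e2$values, e$values, tolerance = 1e-12)
})

test_that("bump amplitude calibration hits the requested stiffness ratio", {
  a <- calibrate_bump_amplitude(31.6 / 60, baseline_delta = 3, span = 142,
                                center = 108, width = 5)
  wt <- generate_flexibility_profile(3, 142)
  mut <- generate_flexibility_profile(3, 142, amplitude = a)
  g_wt <- fit_effective_stiffness(chain_energy_curve(stiffness_from_flexibility(wt)))$gamma
  g_mut <- fit_effective_stiffness(chain_energy_curve(stiffness_from_flexibility(mut)))$gamma
  expect_equal(g_mut / g_wt, 31.6 / 60, tolerance = 1e-6)
})
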