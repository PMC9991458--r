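# Independent oracle used throughout: for springs in series the effective
# stiffness is the inverse summed compliance, 1 / sum(1 / kappa_i).
gamma_series <- function(kappa) 1 / sum(1 / kappa)

test_that("equipartition maps fluctuation to stiffness with the right scale", {
  # delta of 1 radian at 300 K -> kappa = R * T = 2.494 kJ/mol/rad^2
  p <- flexibility_profile("wt", 1:5, rep(180 / pi, 5))
  ch <- stiffness_from_flexibility(p, 300)
  expect_equal(ch$kappa, rep(8.314462618e-3 * 300, 5), tolerance = 1e-12)
  # uniform delta -> uniform kappa; doubling delta quarters kappa
  p2 <- flexibility_profile("wt", 1:5, c(2, 2, 4, 2, 2))
  ch2 <- stiffness_from_flexibility(p2, 300)
  expect_equal(ch2$kappa[3], ch2$kappa[1] / 4, tolerance = 1e-12)
  expect_equal(length(unique(ch2$kappa[-3])), 1L)
})

test_that("chain energy is zero at zero displacement and non-decreasing", {
  set.seed(1)
  ch <- torsional_chain(runif(40, 0.5, 5))
  cv <- chain_energy_curve(ch, seq(0, 35, by = 2.5))
  expect_equal(cv$energy[1], 0)
  expect_true(all(diff(cv$energy) >= 0))
  expect_true(all(is.finite(cv$energy)))
})

test_that("relaxed chain energy equals the series-compliance closed form", {
  # uniform chain: E = 0.5 * (kappa / N) * theta^2
  ch <- torsional_chain(rep(2, 10))
  cv <- chain_energy_curve(ch, c(0, 10, 20, 35))
  th <- cv$theta * pi / 180
  expect_equal(cv$energy, 0.5 * (2 / 10) * th^2, tolerance = 1e-10)
  # heterogeneous chains, up to 200 elements
  set.seed(42)
  for (n in c(2, 7, 50, 200)) {
    kappa <- exp(rnorm(n, 0, 1))
    cv <- chain_energy_curve(torsional_chain(kappa), c(0, 5, 15, 30))
    th <- cv$theta * pi / 180
    expect_equal(cv$energy, 0.5 * gamma_series(kappa) * th^2,
                 tolerance = 1e-9)
  }
})

test_that("fitted gamma equals the series-compliance oracle", {
  set.seed(7)
  for (n in c(3, 20, 142, 200)) {
    kappa <- exp(rnorm(n, 1, 0.8))
    fit <- fit_effective_stiffness(chain_energy_curve(torsional_chain(kappa)))
    expect_lt(abs(fit$gamma - gamma_series(kappa)) / gamma_series(kappa), 1e-6)
  }
})

test_that("stiffness fit round-trips generating gamma on quadratic curves", {
  for (g in c(60, 31.6)) {
    fit <- fit_effective_stiffness(quadratic_energy_curve(g))
    expect_equal(fit$gamma, g, tolerance = 1e-12)
    expect_lt(fit$residual, 1e-20)
  }
})

test_that("noisy quadratic curves recover gamma within the propagated band", {
  g <- 45
  grid <- seq(0, 35, by = 1)
  x <- 0.5 * (grid * pi / 180)^2
  sd_noise <- 0.05
  # linear-in-x fit through origin: SE(gamma) = sd / sqrt(sum(x^2))
  se <- sd_noise / sqrt(sum(x^2))
  set.seed(99)
  est <- replicate(100, {
    cv <- quadratic_energy_curve(g, grid)
    cv$energy <- cv$energy + rnorm(length(grid), 0, sd_noise)
    fit_effective_stiffness(cv)$gamma
  })
  expect_lt(abs(mean(est) - g), 4 * se / sqrt(100))
  expect_lt(abs(sd(est) - se) / se, 0.3)
})

test_that("increasing flexibility at any residue never increases gamma", {
  base <- generate_flexibility_profile(3, 30)
  g0 <- fit_effective_stiffness(chain_energy_curve(stiffness_from_flexibility(base)))$gamma
  for (i in c(1, 15, 30)) {
    d <- base$delta
    d[i] <- d[i] * 1.5
    g1 <- fit_effective_stiffness(chain_energy_curve(
      stiffness_from_flexibility(flexibility_profile("wt", base$residue, d))))$gamma
    expect_lt(g1, g0)
  }
})

test_that("mutant-emulating profile yields lower gamma than wild type", {
  wt <- generate_flexibility_profile(3, 142, genotype = "wt")
  mut <- generate_flexibility_profile(3, 142, amplitude = 7.9, genotype = "s215l")
  g_wt <- fit_effective_stiffness(chain_energy_curve(stiffness_from_flexibility(wt)))$gamma
  g_mut <- fit_effective_stiffness(chain_energy_curve(stiffness_from_flexibility(mut)))$gamma
  expect_lt(g_mut, g_wt)
})

test_that("degenerate inputs are rejected", {
  ch <- torsional_chain(c(1, 1))
  expect_error(chain_energy_curve(ch, c(0, 40)), "\\[0, 35\\]")
  expect_error(chain_energy_curve(ch, c(5, 10)), "start at 0")
  flat <- quadratic_energy_curve(0)
  expect_error(fit_effective_stiffness(flat), "undefined")
  p <- flexibility_profile("wt", 1:3, c(1, 1, 1))
  p$delta[2] <- 0  # bypass constructor to hit the explicit guard
  expect_error(stiffness_from_flexibility(p), "infinite stiffness")
})
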