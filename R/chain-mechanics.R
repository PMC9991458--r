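# Coarse-grained tropomyosin chain mechanics: each half-molecule is a cable
# of torsional springs, one spring element per residue, resisting azimuthal
# displacement on the actin surface. Pinning one end and displacing the other
# through theta in [0, 35] degrees yields a chain energy curve whose
# quadratic coefficient is the effective chain stiffness gamma.

#' Construct a torsional-spring chain
#'
#' @param kappa Per-element torsional stiffness, kJ mol^-1 rad^-2; all `> 0`,
#'   length `>= 2`.
#' @param temperature Temperature in kelvin associated with the chain.
#' @return An object of class `torsional_chain`.
#' @export
torsional_chain <- function(kappa, temperature = 300) {
  if (length(kappa) < 2L) stopf("a chain needs at least 2 spring elements")
  if (!all(is.finite(kappa)) || any(kappa <= 0)) {
    stopf("`kappa` must be finite and strictly positive")
  }
  check_scalar_number(temperature, "temperature")
  if (temperature <= 0) stopf("`temperature` must be > 0 K")
  structure(list(kappa = as.numeric(kappa), temperature = temperature),
            class = "torsional_chain")
}

#' Per-residue stiffness from a flexibility profile
#'
#' Maps each residue's angular fluctuation to a torsional stiffness by
#' equipartition: a harmonic torsional spring at temperature T has
#' `<delta^2> = RT / kappa`, so `kappa = RT / <delta^2>` with delta converted
#' from degrees to radians. More flexible residues are softer; stiffness is
#' monotone decreasing in delta.
#'
#' @param profile A [flexibility_profile()] (delta in degrees).
#' @param temperature Kelvin; `> 0`.
#' @return A [torsional_chain()] with one element per residue, kappa in
#'   kJ mol^-1 rad^-2.
#' @export
stiffness_from_flexibility <- function(profile, temperature = 300) {
  stopifnot(inherits(profile, "flexibility_profile"))
  check_scalar_number(temperature, "temperature")
  if (temperature <= 0) stopf("`temperature` must be > 0 K")
  if (any(profile$delta == 0)) {
    stopf("flexibility of exactly 0 implies infinite stiffness; delta must be > 0")
  }
  delta_rad <- profile$delta * pi / 180
  kappa <- .R_KJ * temperature / delta_rad^2
  torsional_chain(kappa, temperature)
}

#' Minimum chain energy over an azimuthal displacement sweep
#'
#' One end of the chain is pinned at 0 and the other displaced to each theta
#' in the grid; internal node angles relax to the minimum of
#' `sum(0.5 * kappa_i * (phi_i - phi_{i-1})^2)`. The minimizer is exact: the
#' stationarity conditions form a symmetric tridiagonal linear system that is
#' solved directly at each grid point.
#'
#' @param chain A [torsional_chain()].
#' @param theta_grid Ascending grid of end displacements in degrees, within
#'   `[0, 35]` and starting at 0.
#' @return An object of class `chain_energy_curve`: data frame with columns
#'   `theta` (degrees) and `energy` (kJ/mol).
#' @export
chain_energy_curve <- function(chain, theta_grid = seq(0, 35, by = 1)) {
  stopifnot(inherits(chain, "torsional_chain"))
  if (length(theta_grid) < 1L || is.unsorted(theta_grid, strictly = TRUE)) {
    stopf("`theta_grid` must be strictly ascending")
  }
  if (theta_grid[1] != 0) stopf("`theta_grid` must start at 0")
  if (any(theta_grid < 0 | theta_grid > 35)) {
    stopf("`theta_grid` must lie within [0, 35] degrees")
  }
  kappa <- chain$kappa
  n <- length(kappa)  # number of spring elements; n + 1 node angles
  # Internal nodes 1..(n-1); A phi = b with A tridiagonal.
  energy <- vapply(theta_grid, function(theta_deg) {
    theta <- theta_deg * pi / 180
    if (theta == 0) return(0)
    if (n == 1L) return(0.5 * kappa[1] * theta^2)
    m <- n - 1L
    A <- matrix(0, m, m)
    for (i in seq_len(m)) {
      A[i, i] <- kappa[i] + kappa[i + 1L]
      if (i < m) {
        A[i, i + 1L] <- -kappa[i + 1L]
        A[i + 1L, i] <- -kappa[i + 1L]
      }
    }
    b <- numeric(m)
    b[m] <- kappa[n] * theta
    phi <- solve(A, b)
    ang <- c(0, phi, theta)
    sum(0.5 * kappa * diff(ang)^2)
  }, numeric(1))
  out <- data.frame(theta = as.numeric(theta_grid), energy = energy)
  class(out) <- c("chain_energy_curve", class(out))
  out
}

#' Fit a global effective chain stiffness
#'
#' Least-squares fit of `energy = 0.5 * gamma * theta^2` through the origin.
#' On a noise-free quadratic curve this recovers the generating gamma to
#' machine precision; for a physical chain it equals the series-compliance
#' stiffness `1 / sum(1 / kappa_i)`.
#'
#' @param curve A [chain_energy_curve()] with at least 3 points. `theta` is
#'   interpreted in degrees and converted to radians for the fit.
#' @return An object of class `chain_stiffness_fit`: list with `gamma`
#'   (kJ mol^-1 rad^-2), `gamma_per_deg2` (kJ mol^-1 deg^-2), and `residual`
#'   (sum of squared fit residuals).
#' @export
fit_effective_stiffness <- function(curve) {
  stopifnot(inherits(curve, "chain_energy_curve"))
  if (nrow(curve) < 3L) stopf("need at least 3 curve points to fit gamma")
  if (all(curve$energy == 0)) stopf("all-zero energies: gamma is undefined")
  x <- 0.5 * (curve$theta * pi / 180)^2
  y <- curve$energy
  gamma <- sum(x * y) / sum(x * x)
  if (!is.finite(gamma) || gamma <= 0) stopf("fitted gamma is not positive")
  structure(
    list(gamma = gamma,
         gamma_per_deg2 = gamma * (pi / 180)^2,
         residual = sum((y - gamma * x)^2)),
    class = "chain_stiffness_fit"
  )
}

#' Synthetic quadratic chain-energy curve
#'
#' Generates `energy = 0.5 * gamma * theta^2` on a theta grid (degrees, gamma
#' in kJ mol^-1 rad^-2), for round-trip checks of the stiffness fit.
#'
#' @param gamma Effective stiffness, kJ mol^-1 rad^-2.
#' @param theta_grid Degrees grid as in [chain_energy_curve()].
#' @return A `chain_energy_curve`.
#' @export
quadratic_energy_curve <- function(gamma, theta_grid = seq(0, 35, by = 1)) {
  check_scalar_number(gamma, "gamma")
  out <- data.frame(theta = as.numeric(theta_grid),
                    energy = 0.5 * gamma * (theta_grid * pi / 180)^2)
  class(out) <- c("chain_energy_curve", class(out))
  out
}

#' Write a chain energy curve / stiffness fit
#'
#' @param curve A `chain_energy_curve`.
#' @param fit A `chain_stiffness_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_energy_curve <- function(curve, path) {
  utils::write.table(curve, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_energy_curve
#' @export
write_stiffness_fit <- function(fit, path) {
  jsonlite::write_json(
    list(gamma = fit$gamma, gamma_per_deg2 = fit$gamma_per_deg2,
         residual = fit$residual,
         units = list(gamma = "kJ mol-1 rad-2", gamma_per_deg2 = "kJ mol-1 deg-2")),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
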