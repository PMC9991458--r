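# Synthetic stand-ins for molecular-dynamics outputs: per-residue flexibility
# profiles of the tropomyosin superhelical backbone and interaction-energy
# frame ensembles. These emulate the *shape* of MD-derived inputs so the
# downstream chain-mechanics and energetics stages are fully testable; they
# make no claim about atomistic truth.

#' Construct a per-residue flexibility profile
#'
#' A flexibility profile records the angular fluctuation (delta, degrees) of
#' the tropomyosin superhelical backbone at each residue of a modeled
#' half-molecule. Indices must be contiguous and fluctuation strictly
#' positive.
#'
#' @param genotype Label, e.g. `"wt"` or `"s215l"`.
#' @param residue Integer vector of 1-based residue indices, contiguous and
#'   strictly increasing.
#' @param delta Numeric vector of per-residue angular fluctuations, degrees;
#'   all strictly positive.
#' @return An object of class `flexibility_profile`: a data frame with
#'   columns `residue` and `delta`, and a `genotype` attribute.
#' @export
flexibility_profile <- function(genotype, residue, delta) {
  residue <- as.integer(residue)
  if (length(residue) < 2L) stopf("`residue` must contain at least 2 indices")
  if (any(diff(residue) != 1L)) {
    stopf("`residue` indices must be strictly increasing and contiguous")
  }
  if (length(delta) != length(residue)) {
    stopf("`delta` and `residue` must have equal length")
  }
  if (!all(is.finite(delta)) || any(delta <= 0)) {
    stopf("`delta` must be finite and strictly positive (degrees)")
  }
  out <- data.frame(residue = residue, delta = as.numeric(delta))
  attr(out, "genotype") <- as.character(genotype)
  class(out) <- c("flexibility_profile", class(out))
  out
}

#' Generate a synthetic flexibility profile
#'
#' Baseline fluctuation plus an optional localized Gaussian-shaped bump (in
#' residue index) plus i.i.d. Gaussian noise, truncated to stay positive.
#' The bump emulates a mutation-induced local increase in coiled-coil
#' flexibility near the substitution site.
#'
#' @param baseline_delta Baseline fluctuation, degrees; `> 0`.
#' @param span Number of residues in the modeled half-molecule (default 142,
#'   half of the 284-residue molecule).
#' @param center Residue index of the bump center.
#' @param width Gaussian width of the bump, residues.
#' @param amplitude Bump height at its center, degrees; may be 0 (no bump)
#'   and must exceed `-baseline_delta`.
#' @param noise_sd Standard deviation of additive per-residue noise, degrees.
#' @param seed Integer seed for reproducibility, or `NULL`.
#' @param genotype Label stored on the profile.
#' @return A [flexibility_profile()].
#' @export
generate_flexibility_profile <- function(baseline_delta,
                                         span = 142L,
                                         center = 108L,
                                         width = 5,
                                         amplitude = 0,
                                         noise_sd = 0,
                                         seed = NULL,
                                         genotype = "wt") {
  check_scalar_number(baseline_delta, "baseline_delta")
  if (baseline_delta <= 0) stopf("`baseline_delta` must be > 0 (got %g)", baseline_delta)
  if (!is.numeric(span) || length(span) != 1L || span < 2) {
    stopf("`span` must be a single integer >= 2 (got %s)", format(span))
  }
  check_scalar_number(amplitude, "amplitude")
  if (amplitude <= -baseline_delta) {
    stopf("`amplitude` must exceed -baseline_delta")
  }
  check_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  span <- as.integer(span)
  idx <- seq_len(span)
  bump <- amplitude * exp(-((idx - center)^2) / (2 * width^2))
  noise <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(span, 0, noise_sd))
  } else {
    numeric(span)
  }
  delta <- pmax(baseline_delta + bump + noise, 1e-3)
  flexibility_profile(genotype, idx, delta)
}

#' Solve for the bump amplitude that yields a target stiffness ratio
#'
#' For noise-free profiles, the effective chain stiffness is inversely
#' proportional to the sum of squared per-residue fluctuations (see
#' [fit_effective_stiffness()]), so the mutant/wild-type stiffness ratio for
#' a given bump geometry has a closed form in the bump amplitude. This
#' inverts it: it returns the amplitude for which
#' `gamma(mutant) / gamma(wild type) == target_ratio`.
#'
#' @param target_ratio Desired mutant/WT stiffness ratio, in (0, 1].
#' @inheritParams generate_flexibility_profile
#' @return Bump amplitude in degrees.
#' @export
calibrate_bump_amplitude <- function(target_ratio,
                                     baseline_delta = 3,
                                     span = 142L,
                                     center = 108L,
                                     width = 5) {
  check_scalar_number(target_ratio, "target_ratio")
  if (target_ratio <= 0 || target_ratio > 1) stopf("`target_ratio` must be in (0, 1]")
  idx <- seq_len(as.integer(span))
  g <- exp(-((idx - center)^2) / (2 * width^2))
  s0 <- sum(baseline_delta^2)
  # sum((b + a g)^2) = s0*span + 2 a b sum(g) + a^2 sum(g^2); ratio = span*b^2/that
  target_sum <- span * baseline_delta^2 / target_ratio
  a2 <- sum(g^2)
  a1 <- 2 * baseline_delta * sum(g)
  a0 <- span * baseline_delta^2 - target_sum
  disc <- a1^2 - 4 * a2 * a0
  (-a1 + sqrt(disc)) / (2 * a2)
}

#' Construct an interaction-energy frame ensemble
#'
#' Per-frame actin-tropomyosin (plus troponin I in the blocked state)
#' interaction energies for one genotype and one regulatory state.
#'
#' @param genotype Label.
#' @param state Regulatory state, `"B"` (blocked) or `"C"` (closed).
#' @param values Numeric vector of per-frame energies, kcal/mol; length >= 2.
#' @return An object of class `energy_frames`.
#' @export
energy_frames <- function(genotype, state, values) {
  state <- match.arg(state, c("B", "C"))
  if (length(values) < 2L) stopf("an ensemble needs at least 2 frames")
  if (!all(is.finite(values))) stopf("frame energies must be finite")
  structure(
    list(genotype = as.character(genotype), state = state,
         values = as.numeric(values), n_frames = length(values)),
    class = "energy_frames"
  )
}

#' Sample a Gaussian interaction-energy frame ensemble
#'
#' Draws i.i.d. Gaussian frames with the requested mean and SD, emulating the
#' frame statistics of a structural-simulation ensemble (500 frames by
#' default).
#'
#' @param mean Mean interaction energy, kcal/mol.
#' @param sd Frame standard deviation, kcal/mol; `>= 0`.
#' @param n_frames Number of frames; `>= 2`.
#' @param seed Integer seed, or `NULL`.
#' @param genotype,state Labels stored on the ensemble.
#' @return An [energy_frames()] object.
#' @export
sample_energy_frames <- function(mean, sd, n_frames = 500L, seed = NULL,
                                 genotype = "wt", state = "B") {
  check_scalar_number(mean, "mean")
  check_scalar_number(sd, "sd")
  if (sd < 0) stopf("`sd` must be >= 0")
  if (n_frames < 2) stopf("`n_frames` must be >= 2 (got %s)", format(n_frames))
  vals <- with_seed(seed, stats::rnorm(as.integer(n_frames), mean, sd))
  energy_frames(genotype, state, vals)
}

#' Write / read a flexibility profile as delimited text
#'
#' Two tab-separated columns (`residue`, `delta_degrees`) preceded by header
#' comments recording the genotype and units.
#'
#' @param profile A [flexibility_profile()].
#' @param path File path.
#' @return `write_flexibility_profile()` returns `path` invisibly;
#'   `read_flexibility_profile()` returns a [flexibility_profile()].
#' @export
write_flexibility_profile <- function(profile, path) {
  stopifnot(inherits(profile, "flexibility_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# genotype: %s", attr(profile, "genotype")),
    "# units: degrees",
    "residue\tdelta_degrees"
  ), con)
  utils::write.table(profile, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_flexibility_profile
#' @export
read_flexibility_profile <- function(path) {
  header <- readLines(path, n = 5L)
  gline <- grep("^# genotype:", header, value = TRUE)
  genotype <- if (length(gline)) sub("^# genotype:\\s*", "", gline[1]) else "unknown"
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  flexibility_profile(genotype, df[[1]], df[[2]])
}

#' Write / read an energy frame ensemble
#'
#' One energy value per line (kcal/mol) plus a JSON sidecar (`<path>.json`)
#' carrying genotype, state and frame count.
#'
#' @param ensemble An [energy_frames()] object.
#' @param path File path for the values; the sidecar is `<path>.json`.
#' @return `write_energy_frames()` returns `path` invisibly;
#'   `read_energy_frames()` returns an [energy_frames()] object.
#' @export
write_energy_frames <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "energy_frames"))
  writeLines(format(ensemble$values, digits = 15, trim = TRUE), path)
  jsonlite::write_json(
    list(genotype = ensemble$genotype, state = ensemble$state,
         n_frames = ensemble$n_frames, units = "kcal/mol"),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_energy_frames
#' @export
read_energy_frames <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  vals <- as.numeric(readLines(path))
  energy_frames(meta$genotype, meta$state, vals)
}
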