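# Derived observables: motility-equivalent velocity, Hill fits of
# velocity-pCa relations, and isometric twitch metrics.

#' Convert force to sliding velocity
#'
#' A simple proportionality (effective filament viscosity) between force and
#' velocity: `velocity = viscosity_const * force`. Linear and
#' origin-preserving, so Hill-fit midpoint and steepness are invariant to
#' the constant.
#'
#' @param force Numeric force values (myosin-bound unit counts).
#' @param viscosity_const Velocity per unit force; `> 0`.
#' @return Velocities.
#' @export
force_to_velocity <- function(force, viscosity_const = 1) {
  check_scalar_number(viscosity_const, "viscosity_const")
  if (viscosity_const <= 0) stopf("`viscosity_const` must be > 0")
  viscosity_const * force
}

#' Hill-equation velocity at given pCa
#'
#' `v = vmax / (1 + 10^(n_hill * (pca - pca50)))` (base-10 form standard for
#' calcium-sensitivity curves; velocity falls as pCa rises).
#'
#' @param pca pCa values.
#' @param vmax Maximal velocity.
#' @param pca50 Midpoint pCa.
#' @param n_hill Hill coefficient; `> 0`.
#' @return Velocities.
#' @export
hill_velocity <- function(pca, vmax, pca50, n_hill) {
  vmax / (1 + 10^(n_hill * (pca - pca50)))
}

# Dense grid search used both as starting values and as the non-convergence
# fallback. vmax is conditionally linear and profiled out, so the search is
# exhaustive over (pca50, n_hill) with the residual minimized analytically.
hill_grid_search <- function(pca, v, pca50_grid = seq(4, 9, by = 0.02),
                             n_grid = seq(0.1, 5, by = 0.02)) {
  D <- outer(pca, pca50_grid, "-")
  ssv <- sum(v^2)
  best <- list(sse = Inf)
  for (n in n_grid) {
    shape <- 1 / (1 + 10^(n * D))
    num <- colSums(shape * v)
    den <- colSums(shape^2)
    sse <- ssv - num^2 / den
    i <- which.min(sse)
    if (sse[i] < best$sse) {
      best <- list(vmax = num[i] / den[i], pca50 = pca50_grid[i],
                   n_hill = n, sse = sse[i])
    }
  }
  best
}

#' Fit the Hill equation to velocity-pCa data
#'
#' Nonlinear least squares of `v = vmax / (1 + 10^(n_hill * (pca - pca50)))`
#' via Levenberg-Marquardt, started from (and falling back to, on
#' non-convergence) a dense grid search over `pca50` and `n_hill` with the
#' conditionally-linear `vmax` profiled out. At `pca = pca50` the fitted
#' curve equals `vmax / 2`.
#'
#' @param pca pCa values (at least 4 distinct, spanning the transition).
#' @param velocity Velocities (same length).
#' @return An object of class `hill_fit`: list with `vmax`, `pca50`,
#'   `n_hill`, `covariance` (3x3, or `NULL` for a fallback fit), `converged`,
#'   and `residual` (sum of squares).
#' @export
fit_hill <- function(pca, velocity) {
  if (length(pca) != length(velocity)) stopf("`pca` and `velocity` lengths differ")
  if (length(unique(pca)) < 4L) stopf("need at least 4 distinct pCa values")
  start <- hill_grid_search(pca, velocity)
  df <- data.frame(pca = pca, v = velocity)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ vmax / (1 + 10^(n_hill * (pca - pca50))),
      data = df,
      start = list(vmax = start$vmax, pca50 = start$pca50, n_hill = start$n_hill),
      lower = c(vmax = 0, pca50 = 0, n_hill = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    out <- list(vmax = start$vmax, pca50 = start$pca50, n_hill = start$n_hill,
                covariance = NULL, converged = FALSE, residual = start$sse)
  } else {
    cf <- stats::coef(fit)
    covm <- tryCatch(stats::vcov(fit), error = function(e) NULL)
    out <- list(vmax = unname(cf["vmax"]), pca50 = unname(cf["pca50"]),
                n_hill = unname(cf["n_hill"]), covariance = covm,
                converged = TRUE,
                residual = sum(stats::resid(fit)^2))
  }
  class(out) <- "hill_fit"
  out
}

#' Twitch metrics from a force trajectory
#'
#' Diastolic force is the pre-stimulus mean; peak is the post-stimulus
#' maximum; `time_to_peak` runs from the stimulus to the peak; `rt50` from
#' the peak to the first crossing of `diastolic + 0.5 * (peak - diastolic)`
#' (linear interpolation between samples); `fti` is the trapezoidal integral
#' of force above the diastolic level from the stimulus until force first
#' returns to the diastolic level (or the end of the trace). If the trace
#' never relaxes through the 50% level, `rt50` is `NA` and
#' `rt50_censored = TRUE`.
#'
#' @param traj A `filament_trajectory` (or any data frame with `time` and
#'   `force` columns) spanning baseline through relaxation.
#' @param stimulus_time Stimulus onset, s; defaults to the trajectory's
#'   `stim_time` attribute.
#' @param smooth Odd window length (samples) of a centered moving average
#'   applied before locating the peak and the relaxation crossing. The
#'   default 1 applies no smoothing; ensemble-mean traces with a broad peak
#'   benefit from a small window (e.g. 9) because the raw argmax of a noisy
#'   plateau is ill-conditioned.
#' @return An object of class `twitch_metrics`: list with `diastolic_force`,
#'   `peak_force`, `time_to_peak` (s), `rt50` (s), `rt50_censored`, and
#'   `fti` (force x s).
#' @export
twitch_metrics <- function(traj, stimulus_time = attr(traj, "stim_time"),
                           smooth = 1L) {
  if (is.null(stimulus_time)) stopf("`stimulus_time` is required")
  t <- traj$time
  f <- traj$force
  if (smooth > 1L) {
    if (smooth %% 2L == 0L) stopf("`smooth` must be odd")
    fs <- stats::filter(f, rep(1 / smooth, smooth), sides = 2)
    f <- ifelse(is.na(fs), f, as.numeric(fs))
  }
  pre <- t < stimulus_time
  if (!any(pre)) stopf("trajectory has no pre-stimulus baseline")
  diastolic <- mean(f[pre])
  post <- which(t >= stimulus_time)
  ipk <- post[which.max(f[post])]
  peak <- f[ipk]
  ttp <- t[ipk] - stimulus_time

  half <- diastolic + 0.5 * (peak - diastolic)
  rt50 <- NA_real_
  censored <- TRUE
  if (peak > diastolic && ipk < length(t)) {
    below <- which(f[(ipk + 1L):length(f)] <= half)
    if (length(below)) {
      j <- ipk + below[1L]
      # interpolate between samples j-1 and j
      t_cross <- t[j - 1L] + (half - f[j - 1L]) * (t[j] - t[j - 1L]) /
        (f[j] - f[j - 1L])
      rt50 <- t_cross - t[ipk]
      censored <- FALSE
    }
  }

  # integrate above baseline from stimulus to first return to baseline after
  # the peak (or trace end)
  end_idx <- length(t)
  if (ipk < length(t)) {
    back <- which(f[(ipk + 1L):length(f)] <= diastolic)
    if (length(back)) end_idx <- ipk + back[1L]
  }
  seg <- post[1L]:end_idx
  excess <- pmax(f[seg] - diastolic, 0)
  fti <- sum(diff(t[seg]) * (utils::head(excess, -1) + utils::tail(excess, -1)) / 2)

  structure(
    list(diastolic_force = diastolic, peak_force = peak,
         time_to_peak = ttp, rt50 = rt50, rt50_censored = censored,
         fti = fti),
    class = "twitch_metrics"
  )
}
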