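# Stochastic simulation of the thin filament: 26 regulatory units in series,
# nearest-neighbor coupled through tropomyosin chain strain, driven by a
# constant Ca2+ level or a twitch transient. The fixed-step kinetic
# Monte-Carlo kernel lives in compiled code; this file builds its transition
# tables and protocols.

#' Calcium protocol
#'
#' Either a constant free Ca2+ level or a twitch transient: steady diastolic
#' Ca2+, then from `stim_time` a difference-of-exponentials transient rising
#' to `peak` and decaying back to the diastolic level.
#'
#' @param mode `"constant"` or `"transient"`.
#' @param constant_ca Constant level, uM (constant mode).
#' @param diastolic Diastolic level, uM (transient mode; default 0.1).
#' @param peak Transient peak, uM (default 1).
#' @param tau_rise,tau_decay Rise and decay time constants, s.
#' @param stim_time Stimulus onset, s.
#' @return An object of class `calcium_protocol`.
#' @export
calcium_protocol <- function(mode = c("constant", "transient"),
                             constant_ca = 0.1,
                             diastolic = 0.1, peak = 1,
                             tau_rise = 0.02, tau_decay = 0.15,
                             stim_time = 1) {
  mode <- match.arg(mode)
  if (mode == "constant") {
    if (constant_ca <= 0) stopf("`constant_ca` must be > 0 uM")
  } else {
    if (diastolic <= 0) stopf("`diastolic` must be > 0 uM")
    if (peak < diastolic) stopf("`peak` must be >= `diastolic`")
    if (tau_rise <= 0 || tau_decay <= tau_rise) {
      stopf("need 0 < tau_rise < tau_decay")
    }
  }
  structure(list(mode = mode, constant_ca = constant_ca,
                 diastolic = diastolic, peak = peak,
                 tau_rise = tau_rise, tau_decay = tau_decay,
                 stim_time = stim_time),
            class = "calcium_protocol")
}

#' Free Ca2+ concentration of a protocol at given times
#'
#' @param protocol A [calcium_protocol()].
#' @param t Numeric vector of times, s.
#' @return Ca2+ concentrations, uM.
#' @export
protocol_ca <- function(protocol, t) {
  stopifnot(inherits(protocol, "calcium_protocol"))
  if (protocol$mode == "constant") {
    return(rep(protocol$constant_ca, length(t)))
  }
  u <- t - protocol$stim_time
  tr <- protocol$tau_rise
  td <- protocol$tau_decay
  shape <- ifelse(u <= 0, 0, exp(-u / td) - exp(-u / tr))
  u_peak <- log(td / tr) * tr * td / (td - tr)
  smax <- exp(-u_peak / td) - exp(-u_peak / tr)
  protocol$diastolic + (protocol$peak - protocol$diastolic) * shape / smax
}

# Decompose single-unit rates into a Ca-independent part and a coefficient on
# [Ca] (only Ca2+ association scales with concentration), for every
# (state, neighbor-context) row the kernel can encounter.
build_transition_tables <- function(params) {
  contexts <- c(NA, "B", "C", "M")
  kmax <- 6L
  n_rows <- 24L * 16L
  p_const <- array(0, c(kmax, 16L, 24L))
  p_ca <- array(0, c(kmax, 16L, 24L))
  target <- array(0L, c(kmax, 16L, 24L))
  ntrans <- matrix(0L, 16L, 24L)
  for (li in seq_along(contexts)) {
    for (ri in seq_along(contexts)) {
      nb <- c(contexts[li], contexts[ri])
      Q1 <- build_rate_matrix(params, ca = 1, neighbors = nb)
      Q2 <- build_rate_matrix(params, ca = 2, neighbors = nb)
      coef <- Q2 - Q1
      cons <- Q1 - coef
      ctx <- (li - 1L) * 4L + (ri - 1L) + 1L
      for (s in seq_len(24L)) {
        j <- setdiff(which(Q1[s, ] > 0 | Q2[s, ] > 0), s)
        if (length(j) > kmax) stopf("transition table overflow")
        ntrans[ctx, s] <- length(j)
        if (length(j)) {
          target[seq_along(j), ctx, s] <- j - 1L
          p_const[seq_along(j), ctx, s] <- cons[s, j]
          p_ca[seq_along(j), ctx, s] <- coef[s, j]
        }
      }
    }
  }
  list(p_const = as.numeric(aperm(p_const, c(1, 2, 3))),
       p_ca = as.numeric(aperm(p_ca, c(1, 2, 3))),
       target = as.integer(aperm(target, c(1, 2, 3))),
       ntrans = as.integer(ntrans), kmax = kmax, n_rows = n_rows)
}

default_init_states <- function(params) {
  rep(state_index(0L, 0L, 0L, "B"), params$n_units) - 1L
}

#' Simulate the thin filament
#'
#' Fixed-step kinetic Monte Carlo over `n_units` regulatory units in series.
#' At every step each unit reads its neighbors' current tropomyosin
#' positions (chain strain enters the blocked-closed and closed-open rates)
#' and draws at most one single-factor transition with probability
#' `rate * dt`. Force is the number of units in the myosin-bound state,
#' averaged across trajectories.
#'
#' @param params A [model_parameters()] object.
#' @param protocol A [calcium_protocol()].
#' @param duration Simulated time, s.
#' @param dt Step size, s, or `NULL` to use the largest step satisfying the
#'   exit-rate guard (capped at 2e-5 s). An explicit `dt` must satisfy
#'   `max exit rate * dt <= 0.1`; the guard is enforced and violation is an
#'   error naming the offending state/context.
#' @param n_trajectories Number of independent trajectories; `>= 1`.
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @param record_dt Spacing of recorded force samples, s.
#' @param occupancy_burnin Time, s, discarded before accumulating the
#'   per-state occupancy histogram, or `NULL` to skip occupancy tracking.
#' @param window_start Time, s, from which the per-trajectory mean force
#'   (`traj_mean` attribute) is accumulated.
#' @return An object of class `filament_trajectory`: data frame with columns
#'   `time` (s) and `force` (mean myosin-bound unit count, 0..n_units), with
#'   attributes `occupancy` (length-24 state frequencies), `traj_mean`
#'   (per-trajectory window means), `n_trajectories`, `seed`, `dt`,
#'   `protocol`.
#' @export
simulate_filament <- function(params, protocol, duration,
                              dt = NULL, n_trajectories = 1L, seed = 1L,
                              record_dt = 1e-3,
                              occupancy_burnin = NULL,
                              window_start = 0) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(protocol, "calcium_protocol"))
  if (n_trajectories < 1L) stopf("`n_trajectories` must be >= 1")
  ca_max <- max(protocol_ca(protocol, seq(0, duration, length.out = 501L)))
  mer <- max_exit_rate(params, ca_max)
  if (is.null(dt)) dt <- min(2e-5, 0.099 / mer$rate)
  n_steps <- max(2L, ceiling(duration / dt))
  tgrid <- (seq_len(n_steps) - 1L) * dt
  ca_trace <- protocol_ca(protocol, tgrid)
  if (mer$rate * dt > 0.1) {
    stopf(paste0("dt guard violated: total exit rate %.3g s^-1 at %s gives ",
                 "rate*dt = %.3g > 0.1; reduce dt to <= %.3g s"),
          mer$rate, mer$context, mer$rate * dt, 0.1 / mer$rate)
  }
  tab <- build_transition_tables(params)
  record_every <- max(1L, round(record_dt / dt))
  res <- .sim_filament_cpp(tab$p_const, tab$p_ca, tab$target, tab$ntrans,
                           tab$kmax, params$n_units, ca_trace, dt,
                           as.integer(n_trajectories),
                           as.integer(record_every),
                           default_init_states(params),
                           as.numeric(seed),
                           if (is.null(occupancy_burnin)) -1L
                           else as.integer(round(occupancy_burnin / dt)),
                           as.integer(round(window_start / dt)))
  rec_idx <- seq(1L, n_steps, by = record_every)
  out <- data.frame(time = tgrid[rec_idx], force = res$force)
  attr(out, "occupancy") <- res$occupancy
  attr(out, "traj_mean") <- res$traj_mean
  attr(out, "n_trajectories") <- as.integer(n_trajectories)
  attr(out, "seed") <- seed
  attr(out, "dt") <- dt
  attr(out, "protocol") <- protocol
  class(out) <- c("filament_trajectory", class(out))
  out
}

#' Steady-state force at a fixed pCa
#'
#' Simulates 5 s at constant Ca2+ so the chain reaches its stationary
#' regime, then averages force over the final 25% of the interval.
#'
#' @param params A [model_parameters()] object.
#' @param pca pCa (= -log10 of molar free Ca2+).
#' @param n_trajectories Trajectories in the ensemble mean.
#' @param seed Integer seed.
#' @param duration Simulated seconds (default 5).
#' @param dt Step size, s, or `NULL` to choose the largest step satisfying
#'   the exit-rate guard (capped at 2e-5 s).
#' @return Mean force (myosin-bound unit count) with attributes `se` (the
#'   across-trajectory standard error) and `traj_mean`.
#' @export
steady_state_force <- function(params, pca, n_trajectories = 48L, seed = 1L,
                               duration = 5, dt = NULL) {
  ca <- 10^(6 - pca)
  if (is.null(dt)) {
    dt <- min(2e-5, 0.099 / max_exit_rate(params, ca)$rate)
  }
  protocol <- calcium_protocol("constant", constant_ca = ca)
  traj <- simulate_filament(params, protocol, duration = duration, dt = dt,
                            n_trajectories = n_trajectories, seed = seed,
                            record_dt = duration / 100,
                            window_start = 0.75 * duration)
  tm <- attr(traj, "traj_mean")
  force <- mean(tm)
  attr(force, "se") <- stats::sd(tm) / sqrt(length(tm))
  attr(force, "traj_mean") <- tm
  force
}

#' Steady-state force-pCa curve
#'
#' @param params A [model_parameters()] object.
#' @param pca_grid pCa values to visit.
#' @param n_trajectories,seed,duration As [steady_state_force()]; each pCa
#'   point gets a distinct sub-seed derived from `seed`.
#' @return Data frame with columns `pca`, `force`, `se`.
#' @export
force_pca_curve <- function(params, pca_grid = c(9, 7.5, 7, 6.75, 6.5, 6.25,
                                                 6, 5.75, 5.5, 5, 4.5),
                            n_trajectories = 48L, seed = 1L, duration = 5) {
  rows <- lapply(seq_along(pca_grid), function(i) {
    f <- steady_state_force(params, pca_grid[i],
                            n_trajectories = n_trajectories,
                            seed = seed + i, duration = duration)
    data.frame(pca = pca_grid[i], force = as.numeric(f), se = attr(f, "se"))
  })
  do.call(rbind, rows)
}

#' Simulate an isometric twitch
#'
#' The filament equilibrates at the diastolic Ca2+ level until
#' `protocol$stim_time`, then follows the Ca2+ transient. `n_repeats`
#' independent runs (each an `n_trajectories` ensemble mean) are averaged to
#' further reduce stochastic noise.
#'
#' @param params A [model_parameters()] object.
#' @param protocol A transient [calcium_protocol()].
#' @param duration Total simulated time, s (baseline + twitch).
#' @param n_trajectories Trajectories per run.
#' @param n_repeats Independent runs averaged together.
#' @param seed Integer seed; run r uses `seed + r - 1`.
#' @param dt,record_dt As [simulate_filament()].
#' @return A `filament_trajectory` (ensemble- and repeat-averaged force),
#'   with attribute `stim_time`.
#' @export
simulate_twitch <- function(params, protocol = calcium_protocol("transient"),
                            duration = 2.5, n_trajectories = 200L,
                            n_repeats = 1L, seed = 1L,
                            dt = NULL, record_dt = 2e-3) {
  stopifnot(inherits(protocol, "calcium_protocol"))
  if (protocol$mode != "transient") stopf("`protocol` must be a transient")
  runs <- lapply(seq_len(n_repeats), function(r) {
    simulate_filament(params, protocol, duration = duration, dt = dt,
                      n_trajectories = n_trajectories, seed = seed + r - 1L,
                      record_dt = record_dt)
  })
  out <- runs[[1]]
  if (n_repeats > 1L) {
    out$force <- Reduce(`+`, lapply(runs, `[[`, "force")) / n_repeats
  }
  attr(out, "stim_time") <- protocol$stim_time
  attr(out, "n_repeats") <- as.integer(n_repeats)
  out
}

#' Write a force trajectory as delimited text
#'
#' @param traj A `filament_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(data.frame(time_s = traj$time, mean_force = traj$force),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
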