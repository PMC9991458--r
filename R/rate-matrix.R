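# State space and transition rates of a single regulatory unit.
#
# Each unit is the product of four factors:
#   ca: Ca2+ on troponin C          {0 free, 1 bound}
#   sp: TnI switch peptide on TnC   {0 unbound, 1 bound}
#   ip: TnI inhibitory peptide      {0 bound to actin, 1 released}
#   tm: tropomyosin position        {B blocked, C closed, M myosin-bound}
# giving 2 x 2 x 2 x 3 = 24 enumerable states. Structural constraints make
# eight of them inaccessible: tropomyosin can occupy B only while the
# inhibitory peptide is bound to actin, and myosin can bind (M) only while it
# is released. Only single-factor transitions carry nonzero rate.

TM_LEVELS <- c("B", "C", "M")

#' Enumerate the 24 regulatory-unit states
#'
#' @return Data frame with columns `index` (1..24), `ca`, `sp`, `ip` (0/1)
#'   and `tm` (`"B"`, `"C"`, `"M"`), plus `accessible` marking states allowed
#'   by the structural constraints.
#' @export
regulatory_states <- function() {
  g <- expand.grid(ca = 0:1, sp = 0:1, ip = 0:1, tm = TM_LEVELS,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$index <- seq_len(nrow(g))
  g$accessible <- !(g$tm == "B" & g$ip == 1L) & !(g$tm == "M" & g$ip == 0L)
  g[, c("index", "ca", "sp", "ip", "tm", "accessible")]
}

#' Index of a regulatory-unit state
#'
#' @param ca,sp,ip 0/1 factor levels.
#' @param tm `"B"`, `"C"` or `"M"`.
#' @return Integer index in 1..24, consistent with [regulatory_states()].
#' @export
state_index <- function(ca, sp, ip, tm) {
  tm_i <- match(tm, TM_LEVELS)
  if (anyNA(tm_i)) stopf("`tm` must be one of B, C, M")
  as.integer(1L + ca + 2L * sp + 4L * ip + 8L * (tm_i - 1L))
}

# Azimuthal unit of the tropomyosin position offsets, degrees per count.
# With eta = mu = 9 this places the blocked position 18 degrees to one side
# of closed and the myosin-bound position 18 degrees to the other, within
# the range of azimuthal shifts described for steric-blocking models.
.AZIMUTHAL_UNIT_DEG <- 2

# Azimuthal angle (radians) of each tropomyosin position: C is the
# reference, B sits eta offset counts to one side, M mu counts to the other.
tm_angles <- function(params) {
  c(B = -params$eta, C = 0, M = params$mu) * .AZIMUTHAL_UNIT_DEG * pi / 180
}

# Chain strain energy (kJ/mol) of a unit at tropomyosin angle `theta` given
# its neighbors' angles (NA = free end, zero strain contribution).
strain_energy <- function(theta, nbr_thetas, gamma) {
  nbr <- nbr_thetas[!is.na(nbr_thetas)]
  if (!length(nbr)) return(0)
  sum(0.5 * gamma * (theta - nbr)^2)
}

#' Transition-rate matrix of one regulatory unit
#'
#' Builds the 24 x 24 generator of a single unit at a fixed Ca2+
#' concentration, given the tropomyosin positions of its two neighbors
#' (which enter only through the chain strain on the tropomyosin
#' transitions). Off-diagonal entries are transition rates (s^-1); the
#' diagonal makes rows sum to zero. Only single-factor transitions are
#' nonzero. Tropomyosin transitions use a thermodynamic split: for an
#' equilibrium constant K, reference rate f and strain change dE,
#' `forward = f * K^d * exp(-d * dE / RT)` and
#' `reverse = f * K^(d-1) * exp((1-d) * dE / RT)` with `d = delta_split`,
#' so that `forward / reverse = K * exp(-dE / RT)` exactly. With zero strain
#' the isolated-unit blocked-closed pair therefore has equilibrium constant
#' `kbc`.
#'
#' @param params A [model_parameters()] object.
#' @param ca Free Ca2+ concentration, uM; `> 0`.
#' @param neighbors Length-2 character vector of neighbor tropomyosin
#'   positions (`"B"`, `"C"`, `"M"`) or `NA` for a free end. Default: both
#'   ends free.
#' @return 24 x 24 numeric matrix `Q` with `Q[i, j]` the rate from state i
#'   to state j.
#' @export
build_rate_matrix <- function(params, ca, neighbors = c(NA, NA)) {
  stopifnot(inherits(params, "model_parameters"))
  check_scalar_number(ca, "ca")
  if (ca <= 0) stopf("`ca` must be > 0 uM")
  if (length(neighbors) != 2L) stopf("`neighbors` must have length 2")
  ok <- is.na(neighbors) | neighbors %in% TM_LEVELS
  if (!all(ok)) stopf("`neighbors` entries must be B, C, M or NA")

  st <- regulatory_states()
  ang <- tm_angles(params)
  nbr_thetas <- ifelse(is.na(neighbors), NA_real_, ang[neighbors])
  rt <- .R_KJ * params$temperature
  d <- params$delta_split
  Q <- matrix(0, 24L, 24L)

  tm_rates <- function(K, f, theta_from, theta_to) {
    dE <- strain_energy(theta_to, nbr_thetas, params$gamma) -
      strain_energy(theta_from, nbr_thetas, params$gamma)
    if (K == 0) {
      # Forward transition switched off (e.g. no myosin attachment); keep a
      # finite detachment-side rate at the reference scale.
      return(c(fwd = 0, rev = f * exp((1 - d) * dE / rt)))
    }
    c(fwd = f * K^d * exp(-d * dE / rt),
      rev = f * K^(d - 1) * exp((1 - d) * dE / rt))
  }
  bc <- tm_rates(params$kbc, params$k_ref_bc, ang["B"], ang["C"])
  cm <- tm_rates(params$k_md_plus / params$k_md_minus, params$f_xy,
                 ang["C"], ang["M"])

  for (i in seq_len(24L)) {
    s <- st[i, ]
    if (!s$accessible) next
    put <- function(j, rate) {
      if (rate < 0) {
        warning("negative transition rate clipped to zero", call. = FALSE)
        rate <- 0
      }
      Q[i, j] <<- rate
    }
    # Ca2+ on/off; dissociation attenuated while the switch peptide is bound.
    if (s$ca == 0L) {
      put(state_index(1L, s$sp, s$ip, s$tm), params$k_ca_plus * ca)
    } else {
      put(state_index(0L, s$sp, s$ip, s$tm),
          params$k_ca_minus * if (s$sp == 1L) params$lambda else 1)
    }
    # Switch peptide; binding needs Ca, unbinding attenuated while IP is off
    # actin (both via lambda, keeping every thermodynamic cycle consistent).
    if (s$sp == 0L) {
      put(state_index(s$ca, 1L, s$ip, s$tm),
          params$k_sp_plus * if (s$ca == 1L) 1 else params$lambda)
    } else {
      put(state_index(s$ca, 0L, s$ip, s$tm),
          params$k_sp_minus * if (s$ip == 1L) params$lambda else 1)
    }
    # Inhibitory peptide; release/rebind only while tropomyosin is closed
    # (releasing under B or rebinding under M would create a sterically
    # forbidden combination).
    if (s$ip == 0L && s$tm == "C") {
      put(state_index(s$ca, s$sp, 1L, "C"),
          params$k_ip_plus * if (s$sp == 1L) 1 else params$lambda)
    }
    if (s$ip == 1L && s$tm == "C") {
      put(state_index(s$ca, s$sp, 0L, "C"), params$k_ip_minus)
    }
    # Tropomyosin: B <-> C while IP is on actin, C <-> M while it is off.
    if (s$tm == "B") put(state_index(s$ca, s$sp, s$ip, "C"), bc[["fwd"]])
    if (s$tm == "C" && s$ip == 0L) put(state_index(s$ca, s$sp, s$ip, "B"), bc[["rev"]])
    if (s$tm == "C" && s$ip == 1L) put(state_index(s$ca, s$sp, s$ip, "M"), cm[["fwd"]])
    if (s$tm == "M") put(state_index(s$ca, s$sp, s$ip, "C"), cm[["rev"]])
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Exact stationary distribution of a single uncoupled unit
#'
#' Solves the global-balance linear system `pi Q = 0`, `sum(pi) = 1` on the
#' accessible communicating class of a free-standing unit (both chain ends
#' free). The eight sterically forbidden states carry probability zero. This
#' is the independent oracle for the Monte-Carlo engine.
#'
#' @param params A [model_parameters()] object.
#' @param ca Free Ca2+ concentration, uM.
#' @return Numeric vector of length 24 (probabilities, summing to 1), with
#'   attribute `"Q"` carrying the generator used.
#' @export
stationary_distribution_single_unit <- function(params, ca) {
  Q <- build_rate_matrix(params, ca, neighbors = c(NA, NA))
  adj <- Q > 0
  diag(adj) <- TRUE
  # boolean transitive closure (24 nodes): R[i, j] = j reachable from i
  R <- adj
  for (k in seq_len(24L)) {
    R <- R | (R[, k] %o% R[k, ])
  }
  # stationary mass lives on closed communicating classes: states whose
  # whole reachable set can reach them back
  classes <- unique(apply(R & t(R), 1, which, simplify = FALSE))
  closed <- Filter(function(cl) {
    reach_out <- which(apply(R[cl, , drop = FALSE], 2, any))
    all(reach_out %in% cl)
  }, classes)
  # drop structurally inert singletons (no transitions at all)
  closed <- Filter(function(cl) length(cl) > 1L || any(Q[cl, ] > 0), closed)
  if (length(closed) == 0L) stopf("rate matrix has no recurrent transitions")
  if (length(closed) > 1L) {
    stopf("rate matrix is reducible: disconnected closed state sets %s",
          paste(vapply(closed, function(cl) {
            sprintf("{%s}", paste(cl, collapse = ", "))
          }, ""), collapse = " and "))
  }
  keep <- closed[[1L]]
  Qa <- Q[keep, keep, drop = FALSE]
  n <- length(keep)
  A <- rbind(t(Qa), rep(1, n))
  b <- c(rep(0, n), 1)
  pi_a <- qr.solve(A, b)
  pi_a[pi_a < 0 & pi_a > -1e-12] <- 0
  pi_full <- numeric(24L)
  pi_full[keep] <- pi_a / sum(pi_a)
  attr(pi_full, "Q") <- Q
  pi_full
}

#' Largest total exit rate over states and neighbor contexts
#'
#' Used to enforce the fixed-step integrator guard
#' `max exit rate * dt <= 0.1`.
#'
#' @param params A [model_parameters()] object.
#' @param ca Free Ca2+ concentration, uM (for a transient, pass the peak).
#' @return List with `rate` (s^-1) and `context` (a label naming the state
#'   and neighbor context attaining it).
#' @export
max_exit_rate <- function(params, ca) {
  contexts <- c(NA, TM_LEVELS)
  best <- list(rate = -Inf, context = "")
  st <- regulatory_states()
  for (l in contexts) {
    for (r in contexts) {
      Q <- build_rate_matrix(params, ca, neighbors = c(l, r))
      ex <- -diag(Q)
      i <- which.max(ex)
      if (ex[i] > best$rate) {
        best <- list(
          rate = ex[i],
          context = sprintf("state %d (ca=%d sp=%d ip=%d tm=%s), neighbors %s/%s",
                            i, st$ca[i], st$sp[i], st$ip[i], st$tm[i],
                            ifelse(is.na(l), "-", l), ifelse(is.na(r), "-", r))
        )
      }
    }
  }
  best
}
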