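test_that("state enumeration is a bijection over the 2x2x2x3 product", {
  st <- regulatory_states()
  expect_equal(nrow(st), 24L)
  idx <- state_index(st$ca, st$sp, st$ip, st$tm)
  expect_equal(idx, st$index)
  expect_equal(sort(idx), 1:24)
  expect_equal(sum(st$accessible), 16L)
})

test_that("generator rows sum to zero with nonnegative off-diagonals", {
  p <- model_parameters()
  for (nb in list(c(NA, NA), c("B", "B"), c("C", "M"), c("M", NA))) {
    Q <- build_rate_matrix(p, ca = 1, neighbors = nb)
    expect_equal(rowSums(Q), rep(0, 24), tolerance = 1e-10)
    off <- Q; diag(off) <- 0
    expect_true(all(off >= 0))
  }
})

test_that("only single-factor transitions carry nonzero rate", {
  st <- regulatory_states()
  Q <- build_rate_matrix(model_parameters(), ca = 5, neighbors = c("B", "C"))
  for (i in 1:24) for (j in 1:24) {
    if (i == j || Q[i, j] == 0) next
    changed <- sum(st$ca[i] != st$ca[j], st$sp[i] != st$sp[j],
                   st$ip[i] != st$ip[j], st$tm[i] != st$tm[j])
    expect_equal(changed, 1L)
  }
})

test_that("isolated-unit blocked-closed pair has equilibrium constant kbc", {
  for (kbc in c(0.76, 0.97)) {
    p <- model_parameters(kbc = kbc)
    Q <- build_rate_matrix(p, ca = 1, neighbors = c(NA, NA))
    i_b <- state_index(0, 0, 0, "B")
    i_c <- state_index(0, 0, 0, "C")
    expect_equal(Q[i_b, i_c] / Q[i_c, i_b], kbc, tolerance = 1e-12)
    # also with both neighbors in the unit's own position pre/post (zero
    # strain difference requires symmetric context): free ends
    expect_equal(Q[i_b + 2, i_c + 2] / Q[i_c + 2, i_b + 2], kbc,
                 tolerance = 1e-12)
  }
})

test_that("calcium binding flux vanishes in the ca -> 0 limit, unbinding does not", {
  p <- model_parameters()
  Q <- build_rate_matrix(p, ca = 1e-9, neighbors = c(NA, NA))
  on_rate <- Q[state_index(0, 0, 0, "B"), state_index(1, 0, 0, "B")]
  off_rate <- Q[state_index(1, 0, 0, "B"), state_index(0, 0, 0, "B")]
  expect_lt(on_rate, 1e-5)
  expect_equal(off_rate, p$k_ca_minus)
})

test_that("sterically forbidden states are unreachable and absorbing-free", {
  st <- regulatory_states()
  Q <- build_rate_matrix(model_parameters(), ca = 1, neighbors = c(NA, NA))
  bad <- which(!st$accessible)
  expect_true(all(Q[bad, ] == 0))
  expect_true(all(Q[, bad] == 0))
})

test_that("stationary distribution solves global balance to high precision", {
  p <- model_parameters()
  for (ca in c(0.01, 0.3, 1, 10)) {
    pi_s <- stationary_distribution_single_unit(p, ca)
    Q <- attr(pi_s, "Q")
    expect_equal(sum(pi_s), 1, tolerance = 1e-12)
    expect_true(all(pi_s >= 0))
    expect_lt(max(abs(as.numeric(pi_s %*% Q))), 1e-10)
  }
})

test_that("detailed balance holds on the blocked-closed edge without myosin", {
  p <- model_parameters(k_md_plus = 0)
  pi_s <- stationary_distribution_single_unit(p, ca = 0.5)
  Q <- attr(pi_s, "Q")
  st <- regulatory_states()
  for (i in which(st$tm == "B" & st$accessible)) {
    j <- state_index(st$ca[i], st$sp[i], st$ip[i], "C")
    expect_equal(pi_s[i] * Q[i, j], pi_s[j] * Q[j, i], tolerance = 1e-10)
  }
})

test_that("myosin-bound occupancy rises monotonically from pCa 9 to 4", {
  p <- model_parameters()
  pcas <- seq(9, 4, by = -0.5)
  pm <- vapply(pcas, function(x) {
    sum(stationary_distribution_single_unit(p, 10^(6 - x))[17:24])
  }, numeric(1))
  expect_true(all(diff(pm) > 0))
})

test_that("the exit-rate guard reports the binding-saturated context", {
  p <- model_parameters()
  mer <- max_exit_rate(p, ca = 100)
  expect_gt(mer$rate, p$k_ca_plus * 100)
  expect_match(mer$context, "state")
})
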