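# Shared helpers for the suite.

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}

# Continuous-model magnitude of the front-end, independent of
# analog_transfer()'s complex arithmetic: direct magnitude formula.
href_mag <- function(f, cfg = sensor_config()) {
  x <- cfg$tau_hp * 2 * pi * f
  y <- cfg$tau_lp * 2 * pi * f
  cfg$g1 * cfg$g2 * x^2 / (1 + x^2) / (1 + y^2)^1.5
}

# Brute-force two-sided rank-sum p-value by full enumeration of group
# labelings (oracle for the DP-based exact method).
ranksum_brute_p <- function(x, y) {
  n <- length(x); N <- n + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)])
  combos <- utils::combn(N, n)
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  pl <- mean(ws <= w_obs + 1e-9)
  pu <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(pl, pu))
}

# Brute-force signed-rank p over all 2^n sign patterns.
signedrank_brute_p <- function(x, y) {
  d <- (x - y); d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  pl <- mean(vs <= v_obs + 1e-9)
  pu <- mean(vs >= v_obs - 1e-9)
  min(1, 2 * min(pl, pu))
}

# Reference cohort table (subjects x conditions x channels).
ref_cohort <- function() load_fixture("cohort_beta")
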