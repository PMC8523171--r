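# Independent oracles used across the suite.

# Brute-force microstate partition function for an n-site lattice with
# intrinsic per-site association constant ka = 1/k and all-pairs intrinsic
# cooperativity omega: enumerates all 2^n occupancy vectors, weighting a
# state with j occupied sites by ka^j * omega^choose(j, 2) * p^j.
microstate_fractions <- function(n, k_intrinsic, omega, p) {
  ka <- 1 / k_intrinsic
  states <- expand.grid(rep(list(0:1), n))
  j <- rowSums(states)
  w <- ka^j * omega^choose(j, 2) * p^j
  Z <- sum(w)
  vapply(0:n, function(jj) sum(w[j == jj]) / Z, numeric(1))
}

# Macroscopic step Kd's implied by the same intrinsic parameterization:
# beta_j = choose(n, j) * ka^j * omega^choose(j, 2); Kd_j = beta_{j-1}/beta_j.
macroscopic_kd <- function(n, k_intrinsic, omega) {
  ka <- 1 / k_intrinsic
  beta <- vapply(0:n, function(j) choose(n, j) * ka^j * omega^choose(j, 2),
                 numeric(1))
  beta[1:n] / beta[2:(n + 1)]
}

# Closed-form mass balance for a two-site model: protein_free is a root of
# the cubic obtained by clearing denominators in
# P = p + R (b1 p + 2 b2 p^2) / (1 + b1 p + b2 p^2).
cubic_protein_free <- function(kd1, kd2, P, R) {
  b1 <- 1 / kd1
  b2 <- 1 / (kd1 * kd2)
  # b2 p^3 + (b1 + 2 R b2 - P b2) p^2 + (1 + R b1 - P b1) p - P = 0
  roots <- polyroot(c(-P, 1 + R * b1 - P * b1, b1 + 2 * R * b2 - P * b2, b2))
  re <- Re(roots)[abs(Im(roots)) < 1e-9 * max(1, abs(Re(roots)))]
  re <- re[re >= -1e-15 & re <= P * (1 + 1e-12)]
  stopifnot(length(re) >= 1)
  max(min(re, P), 0)
}

# Full-enumeration two-sample KS p-value, independent of the package code
# path: statistic via stats::ks.test, enumeration via combn.
ks_permutation_oracle <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  d_obs <- unname(suppressWarnings(stats::ks.test(a, b)$statistic))
  idx <- utils::combn(length(pooled), n1)
  d_all <- apply(idx, 2, function(i) {
    unname(suppressWarnings(stats::ks.test(pooled[i], pooled[-i])$statistic))
  })
  list(statistic = d_obs, p_value = mean(d_all >= d_obs - 1e-12))
}
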