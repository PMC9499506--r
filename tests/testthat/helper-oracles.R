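# Independent oracles and shared fixtures for the test suite.

noiseless_config <- function(seed = 1, ...) {
  sim_config(noise_cv = 0, seed = seed, ...)
}

# Mann-Whitney U statistic of `a` over `b` (number of (a_i, b_j) pairs with
# a_i > b_j), assuming no ties.
u_stat <- function(a, b) sum(outer(a, b, ">"))

# Brute-force two-sided exact p-value by full enumeration of all
# choose(n + m, n) group assignments of the pooled data (no ties).
mw_brute_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  u_obs <- min(u_stat(a, b), u_stat(b, a))
  combs <- utils::combn(length(pooled), n)
  us <- apply(combs, 2, function(idx) {
    min(u_stat(pooled[idx], pooled[-idx]),
        u_stat(pooled[-idx], pooled[idx]))
  })
  # 2 * P(min-U <= observed min-U) under the permutation null, capped.
  # min-U <= u is equivalent to U <= u or U >= nm - u, so this equals
  # 2 * P(U <= u_obs) by symmetry of the U null distribution.
  u_lo <- apply(combs, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  min(1, 2 * mean(u_lo <= u_obs))
}

# Closed-form OLS slope/intercept (the regression oracle).
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Closed-form pooled-variance two-sample t (the t-test oracle).
pooled_t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  c(t = t, p = 2 * pt(-abs(t), df))
}

# Forward two-compartment sink-condition clearance oracle: receiver
# signals for an insert with whole-insert product `ps` (uL/min).
sink_receiver_signals <- function(ps, times = c(20, 40, 60),
                                  donor_conc = 50, receiver_uL = 1500,
                                  cal = 100) {
  ps * donor_conc * diff(c(0, times)) / receiver_uL * cal
}
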