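# Shared helpers for the suite. All fixtures are built in code.

# Post-burn-in counts of a fresh simulation.
stationary_counts <- function(m, h, n_bins, seed, dt = 4) {
  burn <- burn_in_bins(m)
  tr <- simulate_branching(m = m, h = h, n_bins = n_bins + burn, dt = dt,
                           seed = seed)
  tr$count[-(seq_len(burn))]
}

# Standard error of the mean of an AR(1)-correlated series with lag-1
# correlation m and marginal variance v: var(mean) ~ (v/n) (1+m)/(1-m).
se_mean_ar1 <- function(v, n, m) sqrt(v / n * (1 + m) / (1 - m))

# Bartlett approximation to the variance of the empirical lag-k
# autocorrelation of an AR(1) process with parameter m.
se_acf_ar1 <- function(m, k, n) {
  if (m == 0) return(sqrt(1 / n))
  v <- ((1 + m^2) * (1 - m^(2 * k)) / (1 - m^2) - 2 * k * m^(2 * k)) / n
  sqrt(pmax(v, 1 / n))
}

empirical_acf <- function(x, k_max) {
  drop(stats::acf(x, lag.max = k_max, plot = FALSE, demean = TRUE)$acf)[-1]
}

# Random valid goal-function spec: beta_minus > beta_plus and
# 0 < alpha_prime < beta_plus / beta_minus.
random_goal_spec <- function() {
  beta_plus <- runif(1, 0.2, 2.5)
  beta_minus <- beta_plus * runif(1, 1.3, 3)
  alpha_max <- beta_plus / beta_minus
  alpha_prime <- runif(1, 0.05 * alpha_max, 0.95 * alpha_max)
  list(alpha_prime = alpha_prime, beta_plus = beta_plus,
       beta_minus = beta_minus)
}
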