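#' Standard deviation of the single-neuron efficacy
#'
#' Synaptic weights fluctuate over hours and days with a coefficient of
#' variation of roughly 50% (`cv_w = sigma_w / w ~ 0.5`). If these
#' fluctuations are not strongly correlated across a neuron's `k`
#' outgoing synapses, the variance of the single-neuron efficacy
#' `m_i ~ k * w` scales as `sigma_mi^2 ~ k * sigma_w^2`, giving
#' `sigma_mi ~ cv_w * m_i / sqrt(k)` (about `0.5 m / sqrt(k)` at the
#' measured variability). An optional pairwise correlation `rho` across
#' synapses inflates the variance by `1 + rho * (k - 1)` for sensitivity
#' analysis.
#'
#' @param k_synapses Outgoing synapses per neuron (integer `>= 1`;
#'   cortical order of magnitude is 10,000).
#' @param m Mean neural efficacy (default 1, the worst case at the edge
#'   of stability).
#' @param cv_w Synaptic-weight coefficient of variation (default 0.5).
#' @param rho Pairwise correlation of synaptic fluctuations (default 0).
#' @return Standard deviation of `m_i` (dimensionless).
#' @examples
#' single_neuron_efficacy_sd(k_synapses = 10000) # 0.005
#' @export
single_neuron_efficacy_sd <- function(k_synapses, m = 1, cv_w = 0.5, rho = 0) {
  if (!is.numeric(k_synapses) || any(k_synapses < 1)) {
    abort("`k_synapses` must be >= 1")
  }
  check_nonneg(m, "m"); check_nonneg(cv_w, "cv_w")
  if (any(rho < 0) || any(rho > 1)) abort("`rho` must be in [0, 1]")
  cv_w * m / sqrt(k_synapses) * sqrt(1 + rho * (k_synapses - 1))
}

#' Safety margin from criticality
#'
#' Ongoing synaptic turnover jitters every neuron's efficacy; to stay
#' stable despite these fluctuations the network must keep its operating
#' point a few standard deviations below the critical point `m = 1`. The
#' margin is `n_sigma * sigma_mi`: with 50% synaptic variability, 10,000
#' synapses per neuron and a three-sigma margin this is 1.5%, placing the
#' safe operating point `m_safe = 1 - margin = 0.985` inside the
#' reverberating band observed in vivo.
#'
#' @inheritParams single_neuron_efficacy_sd
#' @param n_sigma Margin width in standard deviations (default 3, which
#'   keeps the network stable 99.9% of the time, see
#'   [stability_probability()]).
#' @return A tibble with columns `margin` (distance below `m = 1`),
#'   `margin_pct`, `m_safe = 1 - margin`, `sd_mi`, `n_sigma`,
#'   `stability_prob` and `regime` (classification of `m_safe`).
#' @examples
#' safety_margin(k_synapses = 10000)
#' @export
safety_margin <- function(k_synapses, m = 1, cv_w = 0.5, n_sigma = 3, rho = 0) {
  if (any(n_sigma < 0)) abort("`n_sigma` must be >= 0")
  sd_mi <- single_neuron_efficacy_sd(k_synapses, m = m, cv_w = cv_w, rho = rho)
  margin <- n_sigma * sd_mi
  tibble(
    k_synapses = k_synapses, cv_w = cv_w, m = m, n_sigma = n_sigma,
    sd_mi = sd_mi, margin = margin, margin_pct = 100 * margin,
    m_safe = 1 - margin,
    stability_prob = stability_probability(n_sigma),
    regime = classify_regime(pmax(1 - margin, 0))
  )
}

#' Probability of staying below the instability line
#'
#' For Gaussian efficacy fluctuations, the probability that the efficacy
#' stays below its mean plus `n_sigma` standard deviations is the
#' one-sided normal tail `pnorm(n_sigma)`: a three-sigma margin keeps the
#' network stable 99.9% of the time.
#'
#' @param n_sigma Margin width in standard deviations (`>= 0`).
#' @return Probability in `[0.5, 1)`, vectorized.
#' @examples
#' stability_probability(3) # 0.99865
#' @export
stability_probability <- function(n_sigma) {
  if (!is.numeric(n_sigma) || any(n_sigma < 0)) abort("`n_sigma` must be >= 0")
  pnorm(n_sigma)
}

#' Goal function for task-dependent tuning of the efficacy
#'
#' Near criticality many network properties diverge as `(1 - m)^-beta`
#' with property-specific exponents; some (sensitivity, timescale,
#' amplification) are desirable for a task, others (trial-to-trial
#' variability, slow equilibration) detrimental. The trade-off is
#' expressed as
#' `Phi_alpha(m) = (1 - m)^-beta_plus - alpha' * (1 - m)^-beta_minus`,
#' where `alpha'` is the rescaled task weight absorbing the properties'
#' normalization constants. Its maximizer is the task-optimal efficacy
#' [optimal_m()].
#'
#' @param m Neural efficacy in `(0, 1)`, vectorized.
#' @param alpha_prime Rescaled weight of the detrimental term (`>= 0`).
#' @param beta_plus Scaling exponent of the desirable property (`> 0`).
#' @param beta_minus Scaling exponent of the detrimental property (`> 0`).
#' @return Goal-function value, vectorized over `m`.
#' @examples
#' goal_function(0.9, alpha_prime = 0.05, beta_plus = 1, beta_minus = 2) # 5
#' @export
goal_function <- function(m, alpha_prime, beta_plus, beta_minus) {
  if (any(m <= 0) || any(m >= 1)) abort("`m` must lie strictly in (0, 1)")
  check_goal_spec(alpha_prime, beta_plus, beta_minus)
  (1 - m)^(-beta_plus) - alpha_prime * (1 - m)^(-beta_minus)
}

check_goal_spec <- function(alpha_prime, beta_plus, beta_minus) {
  if (!is.numeric(alpha_prime) || alpha_prime < 0) abort("`alpha_prime` must be >= 0")
  if (!is.numeric(beta_plus) || beta_plus <= 0) abort("`beta_plus` must be > 0")
  if (!is.numeric(beta_minus) || beta_minus <= 0) abort("`beta_minus` must be > 0")
  invisible(NULL)
}

#' Task-optimal neural efficacy (closed form)
#'
#' Maximizing the [goal_function()] in `m` gives
#' `m* = 1 - (alpha' * beta_minus / beta_plus)^(-1 / (beta_plus - beta_minus))`.
#' The stationary point is an interior maximum only when the detrimental
#' property diverges faster than the desirable one (`beta_minus >
#' beta_plus`) and the weight satisfies `0 < alpha' < beta_plus /
#' beta_minus`; outside that region the value is returned with
#' `valid = FALSE` rather than clipped. With `alpha' = 0` (detrimental
#' aspects ignored) the optimum sits at the critical point, `m* = 1`;
#' any positive weight pushes it into the subcritical regime.
#'
#' @inheritParams goal_function
#' @return A tibble with columns `m_star`, `valid` (interior maximum in
#'   `(0, 1)`), `is_max` (second-order check) and the spec parameters.
#' @examples
#' optimal_m(alpha_prime = 0.05, beta_plus = 1, beta_minus = 2) # m* = 0.9
#' @export
optimal_m <- function(alpha_prime, beta_plus, beta_minus) {
  check_goal_spec(alpha_prime, beta_plus, beta_minus)
  if (beta_plus == beta_minus) abort("degenerate exponents: beta_plus == beta_minus")
  if (alpha_prime == 0) {
    return(tibble(alpha_prime = alpha_prime, beta_plus = beta_plus,
                  beta_minus = beta_minus, m_star = 1, valid = TRUE,
                  is_max = TRUE))
  }
  x_star <- (alpha_prime * beta_minus / beta_plus)^(-1 / (beta_plus - beta_minus))
  m_star <- 1 - x_star
  interior <- is.finite(m_star) && m_star > 0 && m_star < 1
  is_max <- FALSE
  if (interior) {
    # second-order condition in x = 1 - m at the stationary point
    x <- x_star
    d2 <- beta_plus * (beta_plus + 1) * x^(-beta_plus - 2) -
      alpha_prime * beta_minus * (beta_minus + 1) * x^(-beta_minus - 2)
    is_max <- d2 < 0
  }
  tibble(alpha_prime = alpha_prime, beta_plus = beta_plus,
         beta_minus = beta_minus, m_star = m_star,
         valid = interior && is_max, is_max = is_max)
}

#' Task-optimal neural efficacy (grid-search oracle)
#'
#' Dense grid search for the argmax of the [goal_function()] over
#' `m` in `(grid_step, 1 - grid_step)`. Serves as an independent
#' numerical check of the closed form [optimal_m()]; a maximum landing on
#' the grid edge is reported as non-interior.
#'
#' @inheritParams goal_function
#' @param grid_step Grid resolution in `(0, 0.01]` (default `1e-5`).
#' @return A tibble with `m_star`, `phi_star` and `interior` (whether the
#'   argmax is strictly inside the grid).
#' @export
optimal_m_numeric <- function(alpha_prime, beta_plus, beta_minus,
                              grid_step = 1e-5) {
  check_goal_spec(alpha_prime, beta_plus, beta_minus)
  if (grid_step <= 0 || grid_step > 0.01) abort("`grid_step` must be in (0, 0.01]")
  grid <- seq(grid_step, 1 - grid_step, by = grid_step)
  phi <- (1 - grid)^(-beta_plus) - alpha_prime * (1 - grid)^(-beta_minus)
  i <- which.max(phi)
  tibble(m_star = grid[i], phi_star = phi[i],
         interior = i > 1L && i < length(grid))
}

#' Monte-Carlo check of the safety margin
#'
#' Draws per-neuron efficacies `m_i ~ Normal(m_safe, cv_w * m_safe /
#' sqrt(k))` and reports how often the network-mean efficacy (stability
#' is governed by the mean over neurons, not individual efficacies)
#' stays below 1.
#'
#' @inheritParams safety_margin
#' @param n_neurons Neurons averaged per network (default 100).
#' @param n_draws Monte-Carlo replicates (default `1e5`).
#' @param seed Optional seed.
#' @return A tibble with `frac_stable` (fraction of replicates with mean
#'   efficacy below 1) alongside the margin parameters.
#' @export
simulate_margin_stability <- function(k_synapses, m = 1, cv_w = 0.5,
                                      n_sigma = 3, n_neurons = 100,
                                      n_draws = 1e5, seed = NULL) {
  sm <- safety_margin(k_synapses, m = m, cv_w = cv_w, n_sigma = n_sigma)
  m_safe <- sm$m_safe
  sd_i <- single_neuron_efficacy_sd(k_synapses, m = m_safe, cv_w = cv_w)
  frac <- with_seed(seed, {
    means <- rnorm(n_draws, mean = m_safe, sd = sd_i / sqrt(n_neurons))
    mean(means < 1)
  })
  tibble(k_synapses = k_synapses, m_safe = m_safe, sd_mi = sd_i,
         n_neurons = n_neurons, n_draws = n_draws, frac_stable = frac)
}
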