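test_that("lag slopes vanish for independent activity and decay as m^k otherwise", {
  iid <- simulate_branching(m = 0, h = 10, n_bins = 2e4, seed = 41)
  sl <- lag_slopes(iid, 5)
  expect_true(all(abs(sl$slope) < 3 * sl$se))

  tr <- simulate_branching(m = 0.9, h = 1, n_bins = 1e5, seed = 42)
  sl <- lag_slopes(tr, 3)
  for (k in 1:3) {
    expect_lt(abs(sl$slope[k] - 0.9^k), 3 * sl$se[k],
              label = sprintf("slope at lag %d", k))
  }
})

test_that("thinning attenuates slopes by a common factor, preserving the decay", {
  tr <- simulate_branching(m = 0.9, h = 2, n_bins = 1e5, seed = 43)
  th <- subsample(tr, 0.05, seed = 44)
  sl <- lag_slopes(th, 5)
  expect_lt(sl$slope[1], 0.8)  # strongly attenuated below m = 0.9
  expect_lt(abs(sl$slope[2] / sl$slope[1] - 0.9), 0.05)
})

test_that("lag_slopes rejects degenerate input", {
  const <- activity_trace(rep(3L, 100), dt = 4)
  expect_error(lag_slopes(const, 5), "zero variance")
  short <- activity_trace(rpois(50, 5), dt = 4)
  expect_error(lag_slopes(short, 5), "too short")
})

test_that("fit_exponential inverts exact geometric slopes", {
  sl <- tibble::tibble(k = 1:20, slope = 0.5 * 0.98^(1:20))
  fit <- fit_exponential(sl, dt = 4)
  expect_equal(fit$m_hat, 0.98, tolerance = 1e-8)
  expect_equal(fit$b_hat, 0.5, tolerance = 1e-8)
  expect_equal(fit$tau_hat, -4 / log(0.98), tolerance = 1e-8)
  expect_true(fit$converged)

  sl2 <- tibble::tibble(k = 1:10, slope = 0.9^(1:10))
  fit2 <- fit_exponential(sl2, dt = 4)
  expect_equal(fit2$m_hat, 0.9, tolerance = 1e-8)
  expect_equal(fit2$b_hat, 1.0, tolerance = 1e-8)

  expect_error(fit_exponential(tibble::tibble(k = 1:2, slope = c(0.5, 0.25)), 4),
               "at least 3")
})

test_that("round trip recovers (b, m) to six significant digits across the family", {
  set.seed(77)
  for (i in 1:25) {
    b <- runif(1, 0.05, 1)
    m <- runif(1, 0.05, 0.99)
    fit <- fit_exponential(tibble::tibble(k = 1:15, slope = b * m^(1:15)), 4)
    expect_equal(fit$m_hat, m, tolerance = 1e-6)
    expect_equal(fit$b_hat, b, tolerance = 1e-6)
  }
})

test_that("slopes at the noise floor are reported unconverged, not fitted", {
  iid <- simulate_branching(m = 0, h = 10, n_bins = 2e4, seed = 45)
  fit <- estimate_m(iid, n_boot = 0)
  expect_false(fit$converged)
  expect_lt(abs(fit$m_hat), 0.02)
})

test_that("estimate_m recovers m and stays subsampling-invariant", {
  for (m in c(0.9, 0.95)) {
    errs_full <- errs_thin <- numeric(10)
    for (s in 1:10) {
      tr <- simulate_branching(m = m, h = 2, n_bins = 3e4, seed = 600 + s)
      th <- subsample(tr, 0.05, seed = 700 + s)
      errs_full[s] <- estimate_m(tr, n_boot = 0)$m_hat - m
      errs_thin[s] <- estimate_m(th, n_boot = 0)$m_hat - m
    }
    expect_lt(abs(median(errs_full)), 0.01)
    expect_lt(abs(median(errs_thin)), 0.015)
    expect_lt(median(abs(errs_thin - errs_full)), 0.02)
  }
})

test_that("estimate_m recovers a weakly recurrent process", {
  est <- sapply(1:10, function(s) {
    tr <- simulate_branching(m = 0.5, h = 5, n_bins = 3e4, seed = 800 + s)
    estimate_m(tr, n_boot = 0)$m_hat
  })
  expect_lt(abs(median(est) - 0.5), 0.05)
})

test_that("tau_hat is consistent with m_hat whenever converged", {
  tr <- simulate_branching(m = 0.95, h = 2, n_bins = 3e4, seed = 51)
  fit <- estimate_m(tr, n_boot = 0)
  expect_true(fit$converged)
  expect_equal(exp(-fit$dt / fit$tau_hat), fit$m_hat, tolerance = 1e-12)
})

test_that("the naive lag-1 estimator is unbiased under full sampling but collapses under thinning", {
  tr <- simulate_branching(m = 0.9, h = 2, n_bins = 1e5, seed = 52)
  expect_lt(abs(estimate_m_naive(tr) - 0.9), 0.01)
  tr98 <- simulate_branching(m = 0.98, h = 2, n_bins = 1e5, seed = 53)
  th <- subsample(tr98, 0.05, seed = 54)
  expect_lt(estimate_m_naive(th), 0.9)
  expect_lt(abs(estimate_m(th, k_max = 40, n_boot = 0)$m_hat - 0.98), 0.01)
  expect_identical(estimate_m_naive(subsample(tr98, 1)),
                   estimate_m_naive(tr98))
  expect_error(estimate_m_naive(activity_trace(rep(2L, 50), dt = 4)),
               "zero variance")
})

test_that("bootstrap confidence intervals cover the truth at roughly nominal rate", {
  cover <- sapply(1:40, function(s) {
    tr <- simulate_branching(m = 0.9, h = 2, n_bins = 1e4, seed = 900 + s)
    fit <- estimate_m(tr, k_max = 20, n_boot = 100, seed = 950 + s)
    !is.null(fit$ci) && fit$ci[1] <= 0.9 && 0.9 <= fit$ci[2]
  })
  expect_gte(mean(cover), 0.85)
})

test_that("time-resolved estimation tracks an efficacy switch and flags degenerate input", {
  sch <- data.frame(start_bin = c(1L, 201L), m = c(0.7, 0.95))
  ens <- simulate_trials(100, m = NA, h = 2, n_bins = 400, dt = 4, seed = 61,
                         m_schedule = sch)
  tres <- estimate_m_timeresolved(ens, k_max = 5, window = 10)
  pre <- mean(tres$m_hat[tres$bin >= 50 & tres$bin <= 170], na.rm = TRUE)
  post <- mean(tres$m_hat[tres$bin >= 260 & tres$bin <= 370], na.rm = TRUE)
  expect_lt(abs(pre - 0.7), 0.05)
  expect_lt(abs(post - 0.95), 0.05)

  const <- tibble::tibble(
    trial = rep(1:6, each = 50), bin = rep(1:50, 6), count = 3L)
  expect_error(estimate_m_timeresolved(const, k_max = 3),
               "zero variance across trials")
  few <- tibble::tibble(trial = rep(1:3, each = 50), bin = rep(1:50, 3),
                        count = rpois(150, 5))
  expect_error(estimate_m_timeresolved(few), "too few trials")
})

test_that("stationary ensembles show no trend in the time-resolved estimate", {
  ens <- simulate_trials(100, m = 0.9, h = 2, n_bins = 300, dt = 4, seed = 62)
  tres <- estimate_m_timeresolved(ens, k_max = 5, window = 10)
  ok <- is.finite(tres$m_hat)
  expect_lt(abs(mean(tres$m_hat[ok]) - 0.9), 0.05)
  # trend test on estimates spaced well beyond the pooling window and
  # intrinsic timescale, so the points are effectively independent
  sub <- tres[ok & tres$bin %% 25 == 0, ]
  trend_p <- summary(lm(m_hat ~ bin, data = sub))$coefficients["bin", 4]
  expect_gt(trend_p, 0.05)
})

test_that("tidy and glance expose the fit in broom shape", {
  tr <- simulate_branching(m = 0.9, h = 2, n_bins = 2e4, seed = 63)
  fit <- estimate_m(tr, k_max = 15, n_boot = 50, seed = 64)
  td <- tidy(fit)
  expect_equal(td$term, c("m", "b", "tau"))
  expect_true(is.finite(td$conf.low[1]) && td$conf.low[1] < fit$m_hat)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(all(c("m_hat", "tau_hat", "converged") %in% names(gl)))
})
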