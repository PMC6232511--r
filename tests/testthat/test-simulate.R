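test_that("stationary mean matches h / (1 - m) within 3 standard errors", {
  cases <- list(
    list(m = 0, h = 10, n = 1e5, seed = 1),
    list(m = 0.9, h = 1, n = 1e5, seed = 2),
    list(m = 0.98, h = 2, n = 1e5, seed = 3)
  )
  for (cs in cases) {
    x <- stationary_counts(cs$m, cs$h, cs$n, cs$seed)
    target <- cs$h / (1 - cs$m)
    v <- target / (1 - cs$m^2)
    se <- se_mean_ar1(v, length(x), cs$m)
    expect_lt(abs(mean(x) - target), 3 * se,
              label = sprintf("mean deviation at m = %g", cs$m))
  }
})

test_that("autocorrelation decays as m^k", {
  for (cs in list(list(m = 0.5, seed = 4), list(m = 0.9, seed = 5))) {
    x <- stationary_counts(cs$m, 5, 1e5, cs$seed)
    r <- empirical_acf(x, 10)
    for (k in 1:10) {
      expect_lt(abs(r[k] - cs$m^k), 3 * se_acf_ar1(cs$m, k, length(x)),
                label = sprintf("acf lag %d at m = %g", k, cs$m))
    }
  }
})

test_that("stationary variance increases with m at fixed drive", {
  vars <- sapply(c(0, 0.5, 0.9, 0.98), function(m) {
    mean(sapply(1:20, function(s) var(stationary_counts(m, 2, 2e4, 100 + s))))
  })
  expect_true(all(diff(vars) > 0))
})

test_that("supercritical runs fail loudly with the diverging bin", {
  err <- tryCatch(
    simulate_branching(m = 1.05, h = 1, n_bins = 1e5, seed = 1, cap = 1e4),
    error = function(e) e
  )
  expect_s3_class(err, "reverbkit_divergence")
  expect_true(is.numeric(err$bin) && err$bin > 1)
  # exponential drift: the large majority of seeds diverge well before
  # the bin budget is exhausted
  n_div <- sum(sapply(1:20, function(s) {
    inherits(tryCatch(
      simulate_branching(m = 1.05, h = 1, n_bins = 1e5, seed = s, cap = 1e6),
      error = function(e) e), "reverbkit_divergence")
  }))
  expect_gte(n_div, 18)
})

test_that("parameters are validated and seeds reproduce traces", {
  expect_error(simulate_branching(m = -0.1, h = 1, n_bins = 10), "m")
  expect_error(simulate_branching(m = 0.5, h = -1, n_bins = 10), "h")
  expect_error(simulate_branching(m = 0.5, h = 1, n_bins = 1), "n_bins")
  expect_error(simulate_branching(m = NaN, h = 1, n_bins = 10), "m")
  a <- simulate_branching(m = 0.9, h = 1, n_bins = 1000, seed = 9)
  b <- simulate_branching(m = 0.9, h = 1, n_bins = 1000, seed = 9)
  expect_identical(a$count, b$count)
})

test_that("an efficacy schedule switches the stationary level", {
  sch <- data.frame(start_bin = c(1L, 20001L), m = c(0.7, 0.95))
  tr <- simulate_branching(m = NA, h = 2, n_bins = 4e4, seed = 12,
                           m_schedule = sch)
  pre <- tr$count[2000:20000]
  post <- tr$count[24000:40000]
  for (seg in list(list(x = pre, m = 0.7), list(x = post, m = 0.95))) {
    target <- 2 / (1 - seg$m)
    v <- target / (1 - seg$m^2)
    se <- se_mean_ar1(v, length(seg$x), seg$m)
    expect_lt(abs(mean(seg$x) - target), 3 * se)
  }
  expect_error(
    simulate_branching(m = NA, h = 1, n_bins = 100,
                       m_schedule = data.frame(start_bin = c(5L, 10L),
                                               m = c(0.5, 0.9))),
    "start at bin 1")
  expect_error(
    simulate_branching(m = NA, h = 1, n_bins = 100,
                       m_schedule = data.frame(start_bin = c(1L, 10L, 10L),
                                               m = c(0.5, 0.9, 0.2))),
    "strictly increasing")
})

test_that("raster totals are independent of the neuron count", {
  a <- simulate_raster(m = 0.5, h = 5, n_bins = 300, n_neurons = 50, seed = 3)
  b <- simulate_raster(m = 0.5, h = 5, n_bins = 300, n_neurons = 100, seed = 3)
  expect_identical(raster_counts(a)$count, raster_counts(b)$count)
  expect_error(simulate_raster(m = 0.5, h = 5, n_bins = 300, n_neurons = NULL),
               "n_neurons")
})

test_that("raster spike assignment is exchangeable across neurons", {
  # chi-square homogeneity of per-neuron totals under multinomial symmetry
  pvals <- sapply(1:60, function(s) {
    ra <- simulate_raster(m = 0, h = 50, n_bins = 200, n_neurons = 50,
                          seed = 500 + s)
    tot <- tabulate(ra$neuron, nbins = 50)
    suppressWarnings(stats::chisq.test(tot)$p.value)
  })
  expect_gte(mean(pvals > 0.01), 0.9)
})

test_that("binomial thinning scales the mean and keeps identity at 1", {
  tr <- simulate_branching(m = 0.98, h = 2, n_bins = 5e4, seed = 21)
  expect_identical(subsample(tr, 1)$count, tr$count)
  th <- subsample(tr, 0.05, seed = 22)
  expect_lt(abs(mean(th$count) - 0.05 * mean(tr$count)),
            3 * se_mean_ar1(var(th$count), nrow(th), 0.98))
  expect_error(subsample(tr, 0), "fraction")
  expect_error(subsample(tr, 1.2), "fraction")
  expect_error(subsample(tr, 0.5, mode = "neuron_subset"), "spike_raster")
})

test_that("neuron-subset subsampling is deterministic under a fixed seed", {
  ra <- simulate_raster(m = 0.9, h = 2, n_bins = 1000, n_neurons = 40,
                        seed = 31)
  s1 <- subsample(ra, 0.25, mode = "neuron_subset", seed = 7)
  s2 <- subsample(ra, 0.25, mode = "neuron_subset", seed = 7)
  expect_identical(s1$count, s2$count)
  expect_identical(subsample(ra, 1, mode = "neuron_subset", seed = 1)$count,
                   raster_counts(ra)$count)
  expect_error(subsample(ra, 0.01, mode = "neuron_subset"), ">= 1")
})
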