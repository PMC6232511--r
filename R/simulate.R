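#' Simulate a driven branching process
#'
#' Generates binned population spike counts from the driven branching
#' process: each of the `a_t` spikes in bin `t` triggers on average `m`
#' offspring spikes in bin `t + 1`, on top of an external drive of `h`
#' spikes per bin, so that `a_{t+1} | a_t ~ Poisson(m * a_t + h)`. The
#' neural efficacy `m` is the control parameter of the dynamics: `m = 0`
#' gives asynchronous-irregular (i.i.d. Poisson) activity, `0.9 <= m <
#' 0.995` the reverberating regime observed in cortex, `m = 1` the
#' critical point, and `m > 1` unstable dynamics.
#'
#' For `m < 1` the process is stationary after burn-in with mean
#' `h / (1 - m)` and lag-`k` autocorrelation exactly `m^k`; both follow
#' from the Poisson offspring/input model, which the package adopts
#' throughout. For `m >= 1` the expected activity grows without bound, so
#' a hard cap guards the simulation: the run fails loudly with a
#' divergence error naming the offending bin.
#'
#' @param m Neural efficacy (dimensionless, `>= 0`). Ignored when
#'   `m_schedule` is given.
#' @param h Mean external input per bin (spikes/bin, `>= 0`).
#' @param n_bins Number of time bins to simulate (`> 1`).
#' @param dt Bin width in milliseconds; the typical lag of spike
#'   propagation. Default 4 ms.
#' @param seed Optional integer seed; a fixed seed makes the trace
#'   reproducible. The caller's RNG state is left untouched.
#' @param m_schedule Optional piecewise-constant efficacy schedule: a data
#'   frame with columns `start_bin` and `m`, breakpoints strictly
#'   increasing and the first at bin 1. Overrides `m`.
#' @param cap Activity cap (spikes/bin) above which the simulation aborts
#'   with a divergence error. Default `1e6`.
#' @param a0 Optional initial count for bin 1; by default drawn from the
#'   stationary distribution mean `h / (1 - m)` for `m < 1`, else from
#'   `Poisson(h)`.
#'
#' @return An [activity_trace()]; `meta` records the generating parameters.
#' @examples
#' tr <- simulate_branching(m = 0.9, h = 1, n_bins = 5000, seed = 1)
#' mean(tr$count) # close to h / (1 - m) = 10
#' @export
simulate_branching <- function(m, h, n_bins, dt = 4, seed = NULL,
                               m_schedule = NULL, cap = 1e6, a0 = NULL) {
  n_bins <- check_n_bins(n_bins)
  check_nonneg(h, "h")
  if (!is.null(m_schedule)) {
    m_t <- expand_schedule(m_schedule, n_bins)
  } else {
    check_nonneg(m, "m")
    m_t <- rep(m, n_bins)
  }
  counts <- with_seed(seed, branching_core(m_t, h, n_bins, cap, a0))
  activity_trace(counts, dt = dt,
                 meta = list(kind = "simulate_branching", m = if (is.null(m_schedule)) m else NULL,
                             m_schedule = m_schedule, h = h, n_bins = n_bins,
                             dt = dt, seed = seed, cap = cap))
}

branching_core <- function(m_t, h, n_bins, cap, a0 = NULL) {
  counts <- integer(n_bins)
  a <- if (!is.null(a0)) as.integer(a0) else {
    mu0 <- if (m_t[1L] < 1) h / (1 - m_t[1L]) else h
    rpois(1L, mu0)
  }
  counts[1L] <- a
  for (t in seq_len(n_bins - 1L)) {
    a <- rpois(1L, m_t[t] * a + h)
    if (a > cap) {
      abort(sprintf("activity diverged: count %d exceeds cap %g at bin %d",
                    a, cap, t + 1L),
            class = "reverbkit_divergence", bin = t + 1L)
    }
    counts[t + 1L] <- a
  }
  counts
}

expand_schedule <- function(m_schedule, n_bins) {
  sch <- as.data.frame(m_schedule)
  if (!all(c("start_bin", "m") %in% names(sch))) {
    abort("`m_schedule` needs columns `start_bin` and `m`")
  }
  if (sch$start_bin[1L] != 1L) abort("schedule must start at bin 1")
  if (any(diff(sch$start_bin) <= 0)) abort("schedule breakpoints must be strictly increasing")
  if (any(sch$start_bin > n_bins)) abort("schedule breakpoint beyond n_bins")
  check_nonneg(sch$m, "scheduled m")
  idx <- findInterval(seq_len(n_bins), sch$start_bin)
  sch$m[idx]
}

check_n_bins <- function(n_bins) {
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins <= 1 ||
      n_bins != round(n_bins)) {
    abort("`n_bins` must be a single integer > 1")
  }
  as.integer(n_bins)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be finite and >= 0", name))
  }
  invisible(x)
}

# Evaluate `code` under a private RNG stream; caller's state is restored.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Burn-in length for stationary statistics
#'
#' Number of initial bins to discard before treating a simulated trace as
#' stationary: `max(1000, 10 * tau / dt)` bins, since relaxation to the
#' stationary state happens on the intrinsic timescale `tau = -dt/log(m)`.
#'
#' @param m Neural efficacy in `[0, 1)`.
#' @return Integer number of bins.
#' @export
burn_in_bins <- function(m) {
  if (m <= 0) return(1000L)
  if (m >= 1) abort("burn-in undefined for m >= 1")
  max(1000L, as.integer(ceiling(-10 / log(m))))
}

#' Simulate a neuron-resolved spike raster
#'
#' Runs [simulate_branching()] for the population counts and assigns each
#' bin's spikes to neurons by uniform multinomial allocation (the simplest
#' exchangeable assignment for a homogeneous network). With the same
#' `seed`, per-bin totals are identical to [simulate_branching()]
#' regardless of `n_neurons`.
#'
#' @inheritParams simulate_branching
#' @param n_neurons Number of neurons to spread the spikes over (`>= 1`).
#' @return A [spike_raster()] whose per-bin event sums reproduce the
#'   population trace exactly.
#' @export
simulate_raster <- function(m, h, n_bins, n_neurons, dt = 4, seed = NULL,
                            m_schedule = NULL, cap = 1e6) {
  if (missing(n_neurons) || is.null(n_neurons)) abort("`n_neurons` is required")
  n_neurons <- as.integer(n_neurons)
  if (n_neurons < 1L) abort("`n_neurons` must be >= 1")
  n_bins <- check_n_bins(n_bins)
  check_nonneg(h, "h")
  m_t <- if (!is.null(m_schedule)) expand_schedule(m_schedule, n_bins) else {
    check_nonneg(m, "m")
    rep(m, n_bins)
  }
  res <- with_seed(seed, {
    counts <- branching_core(m_t, h, n_bins, cap)
    neuron <- sample.int(n_neurons, sum(counts), replace = TRUE)
    list(counts = counts, neuron = neuron)
  })
  events <- tibble(
    neuron = res$neuron,
    bin = rep.int(seq_len(n_bins), res$counts)
  )
  spike_raster(events, n_neurons = n_neurons, n_bins = n_bins, dt = dt,
               meta = list(kind = "simulate_raster",
                           m = if (is.null(m_schedule)) m else NULL,
                           m_schedule = m_schedule, h = h, seed = seed))
}

#' Simulate a trial-aligned ensemble of traces
#'
#' Repeatedly simulates the same driven branching process (optionally with
#' a time-varying `m_schedule`, e.g. a mid-trial switch of the neural
#' efficacy) and returns the trials in long format, ready for
#' [estimate_m_timeresolved()].
#'
#' @inheritParams simulate_branching
#' @param n_trials Number of aligned trials (`>= 2`).
#' @return A tibble of class `trial_ensemble` with columns `trial`, `bin`,
#'   `count` and a `dt` attribute.
#' @export
simulate_trials <- function(n_trials, m, h, n_bins, dt = 4, seed = NULL,
                            m_schedule = NULL, cap = 1e6) {
  n_trials <- as.integer(n_trials)
  if (n_trials < 2L) abort("`n_trials` must be >= 2")
  n_bins <- check_n_bins(n_bins)
  check_nonneg(h, "h")
  m_t <- if (!is.null(m_schedule)) expand_schedule(m_schedule, n_bins) else {
    check_nonneg(m, "m")
    rep(m, n_bins)
  }
  counts <- with_seed(seed, {
    vapply(seq_len(n_trials), function(i) branching_core(m_t, h, n_bins, cap),
           integer(n_bins))
  })
  out <- new_tibble(
    list(trial = rep(seq_len(n_trials), each = n_bins),
         bin = rep(seq_len(n_bins), times = n_trials),
         count = as.integer(counts)),
    dt = as.numeric(dt),
    meta = list(kind = "simulate_trials", m = if (is.null(m_schedule)) m else NULL,
                m_schedule = m_schedule, h = h, seed = seed),
    class = "trial_ensemble"
  )
  out
}

#' Subsample an activity trace or spike raster
#'
#' Emulates spatial subsampling, i.e. recording only a fraction of the
#' network: either a fixed random subset of neurons (`neuron_subset`, for
#' rasters) or independent retention of each spike with probability
#' `fraction` (`binomial_thinning`). Subsampling biases naive lag-1
#' estimates of the neural efficacy downwards; the multistep regression
#' estimator [estimate_m()] is invariant to it.
#'
#' @param x An [activity_trace()] or [spike_raster()].
#' @param fraction Sampled fraction in `(0, 1]`.
#' @param mode `"binomial_thinning"` (traces and rasters) or
#'   `"neuron_subset"` (rasters only).
#' @param seed Optional integer seed for the subsampling draw.
#' @return An [activity_trace()] of subsampled counts.
#' @export
subsample <- function(x, fraction, mode = c("binomial_thinning", "neuron_subset"),
                      seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    abort("`fraction` must be in (0, 1]")
  }
  UseMethod("subsample")
}

#' @export
subsample.activity_trace <- function(x, fraction,
                                     mode = c("binomial_thinning", "neuron_subset"),
                                     seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "neuron_subset") {
    abort("neuron_subset subsampling needs a spike_raster input")
  }
  if (fraction == 1) return(x)
  counts <- with_seed(seed, rbinom(nrow(x), x$count, fraction))
  activity_trace(counts, dt = trace_dt(x),
                 meta = c(trace_meta(x),
                          list(subsample = list(mode = mode, fraction = fraction,
                                                seed = seed))))
}

#' @export
subsample.spike_raster <- function(x, fraction,
                                   mode = c("binomial_thinning", "neuron_subset"),
                                   seed = NULL) {
  mode <- match.arg(mode)
  n_neurons <- attr(x, "n_neurons")
  n_bins <- attr(x, "n_bins")
  kept <- if (mode == "neuron_subset") {
    n_keep <- round(fraction * n_neurons)
    if (n_keep < 1) abort("fraction * n_neurons must be >= 1")
    keep <- with_seed(seed, sample.int(n_neurons, n_keep))
    x$bin[x$neuron %in% keep]
  } else if (fraction == 1) {
    x$bin
  } else {
    sel <- with_seed(seed, rbinom(nrow(x), 1L, fraction) == 1L)
    x$bin[sel]
  }
  counts <- tabulate(kept, nbins = n_bins)
  activity_trace(counts, dt = attr(x, "dt"),
                 meta = c(trace_meta(x),
                          list(subsample = list(mode = mode, fraction = fraction,
                                                seed = seed))))
}
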