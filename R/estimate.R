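#' Lag-dependent regression slopes of an activity trace
#'
#' For each lag `k = 1..k_max`, computes the ordinary-least-squares slope
#' `r_k` of `a_{t+k}` regressed on `a_t` over all valid `t`. For a fully
#' sampled driven branching process `r_k = m^k`; under spatial subsampling
#' every slope is attenuated by a common factor `b < 1`, so `r_k = b m^k`
#' and the geometric decay in `k` still identifies `m`. These slopes are
#' the raw material of the multistep-regression estimator [estimate_m()].
#'
#' @param trace An [activity_trace()] (or data frame with a `count`
#'   column).
#' @param k_max Largest lag to use; the trace must be longer than
#'   `10 * k_max` bins.
#' @return A tibble with columns `k`, `slope`, `se` (slope standard
#'   error), `n` (pairs used), ordered by `k`.
#' @export
lag_slopes <- function(trace, k_max) {
  x <- as.numeric(trace$count)
  n <- length(x)
  k_max <- as.integer(k_max)
  if (k_max < 1L) abort("`k_max` must be >= 1")
  if (n <= 10L * k_max) abort("trace too short: need length > 10 * k_max")
  if (var(x) == 0) abort("zero variance: constant trace")
  rows <- lapply(seq_len(k_max), function(k) ols_slope(x[1:(n - k)], x[(k + 1):n]))
  out <- bind_rows(rows)
  out$k <- seq_len(k_max)
  out[, c("k", "slope", "se", "n")]
}

ols_slope <- function(xs, ys) {
  n <- length(xs)
  mx <- mean(xs); my <- mean(ys)
  sxx <- sum((xs - mx)^2)
  if (sxx == 0) return(tibble(slope = NA_real_, se = NA_real_, n = n))
  slope <- sum((xs - mx) * (ys - my)) / sxx
  resid <- (ys - my) - slope * (xs - mx)
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  tibble(slope = slope, se = se, n = n)
}

#' Fit the geometric decay of lag slopes
#'
#' Nonlinear least-squares fit of the model `r_k = b * m^k` to a table of
#' lag slopes, by Levenberg-Marquardt with moment-matching start values
#' (`m0 = r_2/r_1` clipped into (0, 1), `b0 = r_1`). `b` absorbs the
#' subsampling attenuation, leaving `m` as the subsampling-invariant
#' neural efficacy; the intrinsic timescale follows as
#' `tau = -dt / log(m)`.
#'
#' An estimate with `m_hat <= 0` or `m_hat >= 1`, or an optimizer
#' failure, is reported with `converged = FALSE` rather than clamped:
#' supercritical data is legal input and must surface as such.
#'
#' @param slopes Tibble from [lag_slopes()] (needs columns `k`, `slope`;
#'   at least 3 finite lags).
#' @param dt Bin width (ms) used to convert `m_hat` into `tau_hat`.
#' @return An object of class `mr_fit`: a list with `m_hat`, `b_hat`,
#'   `tau_hat` (ms; `NA` unless `0 < m_hat < 1`), `slopes` (input table
#'   with a `fitted` column), `k_max`, `dt`, `ci` (filled by
#'   [estimate_m()]), `converged`.
#' @examples
#' sl <- tibble::tibble(k = 1:10, slope = 0.5 * 0.98^(1:10))
#' fit_exponential(sl, dt = 4)
#' @export
fit_exponential <- function(slopes, dt) {
  sl <- slopes[is.finite(slopes$slope), , drop = FALSE]
  if (nrow(sl) < 3L) abort("need at least 3 finite lag slopes")
  # noise floor: when no slope is distinguishable from zero the model
  # b * m^k is unidentifiable (b -> 0 leaves m free); report r_1 flagged
  if ("se" %in% names(sl) && all(is.finite(sl$se)) &&
      all(abs(sl$slope) < 3 * sl$se)) {
    r1 <- sl$slope[which.min(sl$k)]
    tau_hat <- if (r1 > 0 && r1 < 1) -dt / log(r1) else NA_real_
    sl$fitted <- NA_real_
    return(structure(
      list(m_hat = r1, b_hat = NA_real_, tau_hat = tau_hat, slopes = sl,
           k_max = max(sl$k), dt = dt, ci = NULL, n_bins = NA_integer_,
           converged = FALSE),
      class = "mr_fit"
    ))
  }
  r <- sl$slope[order(sl$k)]
  m0 <- if (r[1] > 0 && r[2] > 0) r[2] / r[1] else 0.5
  m0 <- min(max(m0, 0.01), 0.999)
  b0 <- max(r[1], 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(slope ~ b * m^k, data = sl,
                      start = list(b = b0, m = m0),
                      lower = c(b = 1e-12, m = 1e-12),
                      upper = c(b = 10, m = 1.5),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # fall back to log-linear regression on positive slopes
    pos <- sl$slope > 0
    if (sum(pos) >= 3) {
      lf <- lm(log(slope) ~ k, data = sl[pos, ])
      m_hat <- exp(coef(lf)[["k"]])
      b_hat <- exp(coef(lf)[["(Intercept)"]])
      ok <- FALSE
    } else {
      m_hat <- NA_real_; b_hat <- NA_real_; ok <- FALSE
    }
  } else {
    cf <- coef(fit)
    m_hat <- cf[["m"]]
    b_hat <- cf[["b"]]
    ok <- TRUE
  }
  converged <- isTRUE(ok) && is.finite(m_hat) && m_hat > 0 && m_hat < 1
  tau_hat <- if (is.finite(m_hat) && m_hat > 0 && m_hat < 1) -dt / log(m_hat) else NA_real_
  sl$fitted <- if (is.finite(m_hat)) b_hat * m_hat^sl$k else NA_real_
  structure(
    list(m_hat = m_hat, b_hat = b_hat, tau_hat = tau_hat,
         slopes = sl, k_max = max(sl$k), dt = dt, ci = NULL,
         n_bins = NA_integer_, converged = converged),
    class = "mr_fit"
  )
}

#' Estimate the neural efficacy by multistep regression
#'
#' The full subsampling-invariant pipeline: [lag_slopes()] over
#' `k = 1..k_max` followed by [fit_exponential()], with an optional
#' stationary block-bootstrap confidence interval for `m_hat`. Because
#' subsampling only rescales all slopes by a common factor `b`, the fitted
#' `m_hat` recovers the true efficacy even when only a few percent of
#' spikes are observed — where the naive lag-1 slope
#' ([estimate_m_naive()]) underestimates it badly.
#'
#' @inheritParams lag_slopes
#' @param k_max Largest lag; if `NULL`, chosen as
#'   `min(40, ceiling(5 * tau_guess / dt))` with `tau_guess` from the
#'   provisional ratio `r_2 / r_1`, so the fit spans several timescales
#'   without reaching the noise floor.
#' @param n_boot Bootstrap replicates for the CI (default 250; `0` skips
#'   the CI).
#' @param seed Optional seed for the bootstrap.
#' @param conf_level Confidence level (default 0.95).
#' @param dt Bin width (ms); defaults to the trace's own `dt`.
#' @return An `mr_fit` object (see [fit_exponential()]) with `ci` a
#'   two-element vector and `n_bins` filled in.
#' @examples
#' tr <- simulate_branching(m = 0.9, h = 1, n_bins = 2e4, seed = 1)
#' est <- estimate_m(tr, n_boot = 0)
#' est$m_hat
#' @export
estimate_m <- function(trace, k_max = NULL, n_boot = 250, seed = NULL,
                       conf_level = 0.95, dt = NULL) {
  dt <- dt %||% trace_dt(trace)
  if (is.null(k_max)) k_max <- default_k_max(trace)
  sl <- lag_slopes(trace, k_max)
  fit <- fit_exponential(sl, dt)
  fit$n_bins <- nrow(trace)
  if (n_boot > 0) {
    x <- as.numeric(trace$count)
    tau_bins <- if (is.finite(fit$tau_hat)) fit$tau_hat / dt else 20
    # blocks must comfortably exceed the lag range: slopes are computed
    # from pairs within a block only, so joins never dilute the decay
    block <- max(20L, as.integer(ceiling(3 * tau_bins)), k_max + 10L)
    block <- min(block, length(x) - 1L)
    n_blocks <- ceiling(length(x) / block)
    ms <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      starts <- sample.int(length(x) - block + 1L, n_blocks, replace = TRUE)
      bsl <- block_pair_slopes(x, starts, block, k_max)
      bf <- tryCatch(fit_exponential(bsl, dt), error = function(e) NULL)
      if (is.null(bf)) NA_real_ else bf$m_hat
    }, numeric(1)))
    ms <- ms[is.finite(ms)]
    if (length(ms) >= 10) {
      a <- (1 - conf_level) / 2
      fit$ci <- unname(quantile(ms, c(a, 1 - a)))
    }
  }
  fit
}

# Lag slopes of a block-bootstrap replicate, using only pairs whose
# endpoints fall inside the same resampled block.
block_pair_slopes <- function(x, starts, block, k_max) {
  rows <- lapply(seq_len(k_max), function(k) {
    off <- as.vector(outer(0:(block - 1L - k), starts, `+`))
    ols_slope(x[off], x[off + k])
  })
  out <- bind_rows(rows)
  out$k <- seq_len(k_max)
  out
}

default_k_max <- function(trace, dt = NULL) {
  sl <- lag_slopes(trace, 2L)
  r1 <- sl$slope[1]; r2 <- sl$slope[2]
  m_guess <- if (is.finite(r1) && is.finite(r2) && r1 > 0 && r2 > 0) r2 / r1 else NA
  if (!is.finite(m_guess) || m_guess <= 0 || m_guess >= 1) return(10L)
  max(3L, min(40L, as.integer(ceiling(-5 / log(m_guess)))))
}

#' Naive lag-1 estimator of the neural efficacy
#'
#' The conventional estimator: the lag-1 regression slope `r_1` alone.
#' Under full sampling `r_1 = m`, but under spatial subsampling
#' `r_1 = b m` with `b < 1`, so this estimator systematically
#' underestimates `m`. Provided for bias demonstration against
#' [estimate_m()].
#'
#' @inheritParams lag_slopes
#' @return A single numeric estimate.
#' @export
estimate_m_naive <- function(trace) {
  x <- as.numeric(trace$count)
  if (var(x) == 0) abort("zero variance: constant trace")
  ols_slope(x[-length(x)], x[-1])$slope
}

#' Time-resolved efficacy estimation from a trial ensemble
#'
#' In a trial-based design the regression can run across trials instead of
#' across time: at each time bin `t`, `a_{t+k}` is regressed on `a_t`
#' across trials (pooling `window` consecutive onsets), and the resulting
#' slopes are fitted as `b * m^k`. This yields an estimate `m_hat(t)` per
#' evaluable bin and resolves within-trial changes of the neural efficacy,
#' e.g. a mid-trial switch.
#'
#' @param trials A `trial_ensemble` from [simulate_trials()], a long
#'   tibble with columns `trial`, `bin`, `count`, or a list of equal-length
#'   [activity_trace()] objects.
#' @param k_max Largest lag used at each time point (default 5; across
#'   trials the sample per slope is small, so short lag ranges are
#'   preferred).
#' @param window Number of consecutive onset bins pooled per estimate
#'   (default 1 = pure across-trial regression).
#' @param dt Bin width (ms); defaults to the ensemble's `dt` attribute.
#' @return A tibble of class `mr_timeresolved` with columns `bin`,
#'   `m_hat`, `b_hat`, `tau_hat`, `converged`, one row per evaluable bin.
#' @export
estimate_m_timeresolved <- function(trials, k_max = 5, window = 1, dt = NULL) {
  ens <- as_trial_matrix(trials)
  A <- ens$A
  n_bins <- nrow(A); n_trials <- ncol(A)
  if (var(as.vector(A)) == 0) abort("zero variance across trials")
  if (n_trials < 5L) abort("too few trials for across-trial regression (< 5)")
  if (n_trials < 30L) warn("fewer than 30 trials: time-resolved estimates will be noisy")
  dt <- dt %||% ens$dt
  if (is.null(dt)) abort("`dt` not available; pass it explicitly")
  k_max <- as.integer(k_max); window <- as.integer(window)
  if (window < 1L) abort("`window` must be >= 1")
  if (k_max < 3L) abort("`k_max` must be >= 3 to fit the decay")
  t_last <- n_bins - k_max - window + 1L
  if (t_last < 1L) abort("trials too short for this k_max and window")
  any_signal <- FALSE
  rows <- vector("list", t_last)
  for (t in seq_len(t_last)) {
    win <- t:(t + window - 1L)
    xs <- as.vector(A[win, , drop = FALSE])
    if (var(xs) == 0) {
      rows[[t]] <- tibble(bin = t, m_hat = NA_real_, b_hat = NA_real_,
                          tau_hat = NA_real_, converged = FALSE)
      next
    }
    any_signal <- TRUE
    sl <- vapply(seq_len(k_max), function(k) {
      ys <- as.vector(A[win + k, , drop = FALSE])
      ols_slope(xs, ys)$slope
    }, numeric(1))
    fit <- tryCatch(fit_exponential(tibble(k = seq_len(k_max), slope = sl), dt),
                    error = function(e) NULL)
    rows[[t]] <- if (is.null(fit)) {
      tibble(bin = t, m_hat = NA_real_, b_hat = NA_real_,
             tau_hat = NA_real_, converged = FALSE)
    } else {
      tibble(bin = t, m_hat = fit$m_hat, b_hat = fit$b_hat,
             tau_hat = fit$tau_hat, converged = fit$converged)
    }
  }
  if (!any_signal) abort("zero variance across trials at every time point")
  out <- bind_rows(rows)
  new_tibble(as.list(out), dt = as.numeric(dt), k_max = k_max,
             window = window, class = "mr_timeresolved")
}

as_trial_matrix <- function(trials) {
  if (is.matrix(trials)) return(list(A = trials, dt = NULL))
  if (is.data.frame(trials)) {
    if (!all(c("trial", "bin", "count") %in% names(trials))) {
      abort("trial ensemble needs columns `trial`, `bin`, `count`")
    }
    tab <- table(trials$trial)
    if (length(unique(tab)) != 1L) abort("trials must have equal length")
    ids <- unique(trials$trial)
    n_bins <- unname(tab[1L])
    ord <- order(match(trials$trial, ids), trials$bin)
    A <- matrix(as.numeric(trials$count[ord]), nrow = n_bins, ncol = length(ids))
    return(list(A = A, dt = attr(trials, "dt")))
  }
  if (is.list(trials)) {
    lens <- vapply(trials, nrow, integer(1))
    if (length(unique(lens)) != 1L) abort("trials must have equal length")
    dts <- unique(vapply(trials, trace_dt, numeric(1)))
    if (length(dts) != 1L) abort("trials must share the same dt")
    A <- vapply(trials, function(tr) as.numeric(tr$count), numeric(lens[1L]))
    return(list(A = A, dt = dts))
  }
  abort("unsupported trial ensemble input")
}

#' @export
print.mr_fit <- function(x, ...) {
  cat("<mr_fit> multistep-regression estimate\n")
  cat(sprintf("  m_hat = %.4f%s   b_hat = %.4f   tau_hat = %s\n",
              x$m_hat,
              if (!is.null(x$ci)) sprintf(" [%.4f, %.4f]", x$ci[1], x$ci[2]) else "",
              x$b_hat,
              if (is.finite(x$tau_hat)) sprintf("%.1f ms", x$tau_hat) else "NA"))
  cat(sprintf("  lags 1..%d, dt = %g ms, converged = %s\n",
              x$k_max, x$dt, x$converged))
  invisible(x)
}

#' Tidy a multistep-regression fit
#'
#' @param x An `mr_fit` object.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter (`m`, `b`, `tau`) with
#'   `estimate` and, when a bootstrap CI was computed for `m`, `conf.low`
#'   and `conf.high`. `glance()`: a one-row summary.
#' @method tidy mr_fit
#' @export
tidy.mr_fit <- function(x, ...) {
  out <- tibble(
    term = c("m", "b", "tau"),
    estimate = c(x$m_hat, x$b_hat, x$tau_hat),
    conf.low = NA_real_, conf.high = NA_real_
  )
  if (!is.null(x$ci)) {
    out$conf.low[1] <- x$ci[1]
    out$conf.high[1] <- x$ci[2]
  }
  out
}

#' @rdname tidy.mr_fit
#' @method glance mr_fit
#' @export
glance.mr_fit <- function(x, ...) {
  tibble(m_hat = x$m_hat, b_hat = x$b_hat, tau_hat = x$tau_hat,
         k_max = x$k_max, dt = x$dt, n_bins = x$n_bins,
         converged = x$converged)
}
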