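#' Linear-response sensitivity of the network rate
#'
#' How strongly the stationary network rate `r = h / (1 - m)` responds to
#' a change of the external input `h`: `dr/dh = 1 / (1 - m)`. The
#' sensitivity diverges as the neural efficacy approaches the critical
#' point `m = 1`, which is what makes the reverberating regime so
#' tunable: near `m ~ 0.95` a small change of `m` retunes the response
#' several-fold, while the same change near `m = 0.5` barely matters.
#'
#' @param m Neural efficacy, `0 <= m < 1`.
#' @return `1 / (1 - m)` (dimensionless), vectorized over `m`.
#' @examples
#' sensitivity(0.99) / sensitivity(0.94) # six-fold
#' @export
sensitivity <- function(m) {
  check_m_subcritical(m)
  1 / (1 - m)
}

check_m_subcritical <- function(m, allow_zero = TRUE) {
  if (!is.numeric(m) || anyNA(m)) abort("`m` must be numeric and non-missing")
  if (any(m < 0)) abort("`m` must be >= 0")
  if (any(m >= 1)) abort("diverged quantity: requires m < 1")
  invisible(m)
}

#' Intrinsic network timescale
#'
#' The decay constant of the activity autocorrelation,
#' `tau = -dt / log(m)`, approximated near criticality by
#' `dt / (1 - m)`. Input reverberates in the network over this
#' timescale; in the reverberating regime (`m ~ 0.98`, `dt = 4` ms) it
#' reaches hundreds of milliseconds.
#'
#' @param m Neural efficacy, `0 < m < 1`.
#' @param dt Bin width / spike-propagation lag (ms, `> 0`).
#' @return A tibble with columns `tau` (exact, ms), `tau_approx`
#'   (`dt / (1 - m)`), and `rel_diff` (their relative difference).
#' @examples
#' intrinsic_timescale(0.98, dt = 4) # tau ~ 198 ms
#' @export
intrinsic_timescale <- function(m, dt) {
  if (any(!is.numeric(m)) || any(m <= 0) || any(m >= 1)) {
    abort("`m` must lie strictly in (0, 1)")
  }
  if (!is.numeric(dt) || any(dt <= 0)) abort("`dt` must be > 0")
  tau <- -dt / log(m)
  tau_approx <- dt / (1 - m)
  tibble(m = m, dt = dt, tau = tau, tau_approx = tau_approx,
         rel_diff = abs(tau_approx - tau) / tau)
}

#' Neural efficacy implied by a response duration
#'
#' Inverts the timescale relation: the efficacy whose intrinsic timescale
#' equals the observed response duration is `m = exp(-dt / duration)`.
#' A network response outlasting 50 ms with a 4 ms propagation lag, for
#' example, implies `m >= exp(-4/50) ~ 0.923`.
#'
#' @param response_duration Observed response duration (ms, `> 0`).
#' @param dt Spike-propagation lag (ms, `> 0`).
#' @return The implied neural efficacy, vectorized.
#' @export
implied_m <- function(response_duration, dt = 4) {
  if (!is.numeric(response_duration) || any(response_duration <= 0)) {
    abort("`response_duration` must be > 0")
  }
  if (!is.numeric(dt) || any(dt <= 0)) abort("`dt` must be > 0")
  exp(-dt / response_duration)
}

#' Stationary network rate under constant drive
#'
#' `r = h / (1 - m)`: each input spike is amplified by the full geometric
#' cascade of recurrent activations. Linear in `h`, with slope equal to
#' [sensitivity()].
#'
#' @param m Neural efficacy, `0 <= m < 1`.
#' @param h External input (spikes/bin, `>= 0`).
#' @return Stationary rate in spikes/bin.
#' @export
stationary_rate <- function(m, h) {
  check_m_subcritical(m)
  check_nonneg(h, "h")
  h / (1 - m)
}

#' Cumulative amplification of a single injected spike
#'
#' Total number of extra spikes eventually triggered per injected spike:
#' the geometric series `m + m^2 + ... = m / (1 - m)`. (Including the
#' injected spike itself, the total response is `1 / (1 - m)`.) For
#' `m >= 1` a stimulus can be amplified without bound, so the function
#' fails rather than returning infinity.
#'
#' @param m Neural efficacy, `0 <= m < 1`.
#' @param include_input If `TRUE`, count the injected spike itself
#'   (returns `1 / (1 - m)`).
#' @return Dimensionless amplification, vectorized.
#' @export
amplification <- function(m, include_input = FALSE) {
  if (any(m >= 1)) abort("infinite amplification: requires m < 1")
  check_m_subcritical(m)
  if (include_input) 1 / (1 - m) else m / (1 - m)
}

#' Classify the dynamical regime of a neural efficacy
#'
#' Maps `m` to a regime label. The anchors `m = 0`
#' (asynchronous-irregular), the in-vivo reverberating band
#' `0.9 <= m < 0.995`, and `m = 1` (critical) are fixed by observation;
#' the `0.5` cut between asynchronous-irregular and the intermediate
#' subcritical band is this package's convention. All boundaries are
#' configurable.
#'
#' @param m Neural efficacy (`>= 0`), vectorized.
#' @param boundaries Named numeric vector of lower edges for
#'   `subcritical-intermediate`, `reverberating` and `near-critical`.
#' @return A factor with levels `asynchronous-irregular`,
#'   `subcritical-intermediate`, `reverberating`, `near-critical`,
#'   `critical`, `unstable`.
#' @examples
#' classify_regime(c(0, 0.7, 0.98, 0.999, 1, 1.01))
#' @export
classify_regime <- function(m, boundaries = c(intermediate = 0.5,
                                              reverberating = 0.9,
                                              near_critical = 0.995)) {
  if (!is.numeric(m) || anyNA(m)) abort("`m` must be numeric and non-missing")
  if (any(m < 0)) abort("`m` must be >= 0")
  b <- boundaries
  lv <- c("asynchronous-irregular", "subcritical-intermediate",
          "reverberating", "near-critical", "critical", "unstable")
  lab <- ifelse(m > 1, "unstable",
         ifelse(m == 1, "critical",
         ifelse(m >= b[["near_critical"]], "near-critical",
         ifelse(m >= b[["reverberating"]], "reverberating",
         ifelse(m >= b[["intermediate"]], "subcritical-intermediate",
                "asynchronous-irregular")))))
  factor(lab, levels = lv)
}

#' All analytic response properties attached to a neural efficacy
#'
#' One-stop summary combining [sensitivity()], [stationary_rate()],
#' [intrinsic_timescale()], [amplification()] and [classify_regime()].
#'
#' @param m Neural efficacy (`0 <= m < 1` for the divergent quantities),
#'   vectorized.
#' @param h Optional external input (spikes/bin) for the stationary rate.
#' @param dt Optional bin width (ms) for the timescale.
#' @return A tibble with one row per `m`.
#' @examples
#' regime_properties(c(0.9, 0.98), h = 1, dt = 4)
#' @export
regime_properties <- function(m, h = NULL, dt = NULL) {
  check_m_subcritical(m)
  out <- tibble(
    m = m,
    sensitivity = sensitivity(m),
    amplification = amplification(m),
    regime = classify_regime(m)
  )
  if (!is.null(h)) out$stationary_rate <- stationary_rate(m, h)
  if (!is.null(dt)) {
    ts <- intrinsic_timescale(pmax(m, .Machine$double.xmin), dt)
    out$tau <- ifelse(m > 0, ts$tau, 0)
    out$tau_approx <- ifelse(m > 0, ts$tau_approx, dt)
  }
  out
}
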