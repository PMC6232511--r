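#' Plot methods
#'
#' `autoplot()` methods give a quick ggplot2 view of each result type:
#' the population count time series for an [activity_trace()], the spike
#' raster for a [spike_raster()], the lag slopes with the fitted
#' geometric decay for an `mr_fit`, and the `m_hat(t)` time course for a
#' time-resolved estimate.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name reverbkit-autoplot
NULL

#' @rdname reverbkit-autoplot
#' @method autoplot activity_trace
#' @export
autoplot.activity_trace <- function(object, ...) {
  dt <- trace_dt(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin * dt, y = .data$count)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "population count (spikes/bin)") +
    ggplot2::theme_minimal()
}

#' @rdname reverbkit-autoplot
#' @method autoplot spike_raster
#' @export
autoplot.spike_raster <- function(object, ...) {
  dt <- attr(object, "dt")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin * dt, y = .data$neuron)) +
    ggplot2::geom_point(shape = ".", alpha = 0.6) +
    ggplot2::labs(x = "time (ms)", y = "neuron") +
    ggplot2::theme_minimal()
}

#' @rdname reverbkit-autoplot
#' @method autoplot mr_fit
#' @export
autoplot.mr_fit <- function(object, ...) {
  ggplot2::ggplot(object$slopes, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$slope)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(
      x = "lag k (bins)", y = expression(r[k]),
      title = sprintf("r[k] = b m^k fit: m = %.4f, b = %.3f, tau = %s",
                      object$m_hat, object$b_hat,
                      if (is.finite(object$tau_hat))
                        sprintf("%.0f ms", object$tau_hat) else "NA")
    ) +
    ggplot2::theme_minimal()
}

#' @rdname reverbkit-autoplot
#' @method autoplot mr_timeresolved
#' @export
autoplot.mr_timeresolved <- function(object, ...) {
  dt <- attr(object, "dt")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin * dt, y = .data$m_hat)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "trial time (ms)", y = expression(hat(m)(t))) +
    ggplot2::theme_minimal()
}

#' Plot a goal function and its optimum
#'
#' Draws `Phi_alpha(m)` over `(0, 1)` with the closed-form optimum
#' [optimal_m()] marked when it is a valid interior maximum.
#'
#' @inheritParams goal_function
#' @param m_range Range of `m` to draw (kept strictly inside `(0, 1)`).
#' @return A ggplot object.
#' @export
plot_goal_function <- function(alpha_prime, beta_plus, beta_minus,
                               m_range = c(0.01, 0.995)) {
  m <- seq(m_range[1], m_range[2], length.out = 500)
  df <- tibble(m = m,
               phi = goal_function(m, alpha_prime, beta_plus, beta_minus))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$phi)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "neural efficacy m", y = expression(Phi[alpha](m))) +
    ggplot2::theme_minimal()
  opt <- optimal_m(alpha_prime, beta_plus, beta_minus)
  if (isTRUE(opt$valid) && opt$m_star > m_range[1] && opt$m_star < m_range[2]) {
    p <- p + ggplot2::geom_vline(xintercept = opt$m_star,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}
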