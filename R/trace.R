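#' Binned population activity traces
#'
#' An `activity_trace` is a tibble with one row per time bin and columns
#' `bin` (1-based bin index) and `count` (non-negative integer population
#' spike count), carrying the bin width `dt` (milliseconds) and a free-form
#' provenance list `meta` as attributes. All estimators in the package
#' consume this shape; any plain data frame with `bin` and `count` columns
#' can be promoted with `activity_trace()`.
#'
#' @param counts Non-negative integer vector of spike counts, one per bin,
#'   or a data frame with `bin` and `count` columns.
#' @param dt Bin width in milliseconds (must be positive).
#' @param meta Optional named list recording provenance (generating
#'   parameters, source file, ...).
#'
#' @return A tibble of class `activity_trace` with columns `bin`, `count`.
#' @examples
#' tr <- activity_trace(rpois(100, 5), dt = 4)
#' trace_dt(tr)
#' @export
activity_trace <- function(counts, dt, meta = list()) {
  if (is.data.frame(counts)) {
    if (!all(c("bin", "count") %in% names(counts))) {
      abort("data frame input needs `bin` and `count` columns")
    }
    bins <- counts$bin
    counts <- counts$count
  } else {
    bins <- seq_along(counts)
  }
  validate_counts(counts)
  if (length(counts) < 2L) abort("an activity trace needs at least 2 bins")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    abort("`dt` must be a single positive number (ms)")
  }
  new_tibble(
    list(bin = as.integer(bins), count = as.integer(round(counts))),
    dt = as.numeric(dt), meta = meta,
    class = "activity_trace"
  )
}

validate_counts <- function(counts) {
  if (!is.numeric(counts)) abort("counts must be numeric")
  if (anyNA(counts) || any(!is.finite(counts))) abort("counts must be finite")
  if (any(counts < 0)) {
    abort(sprintf("negative count at bin %d", which(counts < 0)[1L]))
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    abort(sprintf("non-integer count at bin %d",
                  which(abs(counts - round(counts)) > 1e-8)[1L]))
  }
  invisible(counts)
}

#' @rdname activity_trace
#' @param x An `activity_trace` (or `spike_raster`).
#' @export
trace_dt <- function(x) {
  dt <- attr(x, "dt")
  if (is.null(dt)) abort("object carries no `dt` attribute; pass dt explicitly")
  dt
}

#' @rdname activity_trace
#' @export
trace_meta <- function(x) attr(x, "meta") %||% list()

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.activity_trace <- function(x, ...) {
  cat(sprintf("<activity_trace> %d bins, dt = %g ms, mean count = %.3f\n",
              nrow(x), attr(x, "dt"), mean(x$count)))
  NextMethod()
}

#' Neuron-resolved spike rasters
#'
#' A `spike_raster` stores spike events as a tibble with columns `neuron`
#' (1-based neuron id) and `bin` (1-based bin index), with `n_neurons`,
#' `n_bins` and `dt` attributes. Summing events per bin reproduces the
#' population [activity_trace()] exactly.
#'
#' @param events Data frame with integer columns `neuron` and `bin`.
#' @param n_neurons,n_bins Dimensions of the raster grid.
#' @param dt Bin width (ms).
#' @param meta Optional provenance list.
#' @return A tibble of class `spike_raster`.
#' @seealso [raster_counts()] to collapse to a population trace.
#' @export
spike_raster <- function(events, n_neurons, n_bins, dt, meta = list()) {
  if (!all(c("neuron", "bin") %in% names(events))) {
    abort("`events` needs `neuron` and `bin` columns")
  }
  n_neurons <- as.integer(n_neurons)
  n_bins <- as.integer(n_bins)
  if (n_neurons < 1L) abort("`n_neurons` must be >= 1")
  if (n_bins < 2L) abort("`n_bins` must be >= 2")
  if (nrow(events) > 0) {
    if (any(events$neuron < 1L | events$neuron > n_neurons)) {
      abort("neuron id outside 1..n_neurons")
    }
    if (any(events$bin < 1L | events$bin > n_bins)) {
      abort("bin index outside 1..n_bins")
    }
  }
  new_tibble(
    list(neuron = as.integer(events$neuron), bin = as.integer(events$bin)),
    n_neurons = n_neurons, n_bins = n_bins, dt = as.numeric(dt), meta = meta,
    class = "spike_raster"
  )
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d neurons x %d bins, dt = %g ms, %d events\n",
              attr(x, "n_neurons"), attr(x, "n_bins"), attr(x, "dt"), nrow(x)))
  NextMethod()
}

#' Collapse a spike raster to its population activity trace
#'
#' @param raster A [spike_raster()].
#' @return The [activity_trace()] of per-bin event sums (zero-count bins
#'   included).
#' @export
raster_counts <- function(raster) {
  n_bins <- attr(raster, "n_bins")
  counts <- tabulate(raster$bin, nbins = n_bins)
  activity_trace(counts, dt = attr(raster, "dt"), meta = trace_meta(raster))
}
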