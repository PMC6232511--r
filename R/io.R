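#' Read and write activity-trace files
#'
#' Traces are stored as plain text: `#`-prefixed header lines carrying at
#' least the bin width (`# dt <ms>`) plus free-form provenance, followed
#' by one integer count per line in bin order. The round trip
#' write-then-read is lossless for counts and `dt`.
#'
#' @param path File path.
#' @param trace An [activity_trace()].
#' @return `read_trace()` returns an [activity_trace()] whose `meta`
#'   holds the header lines; `write_trace()` returns `path` invisibly.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path)
  is_header <- grepl("^#", lines)
  header <- lines[is_header]
  body_idx <- which(!is_header & nzchar(trimws(lines)))
  if (length(body_idx) == 0L) abort("no bins: trace file has no counts")
  dt <- parse_header_value(header, "dt")
  if (is.na(dt)) abort("missing `# dt <ms>` header line")
  vals <- suppressWarnings(as.numeric(trimws(lines[body_idx])))
  bad <- which(!is.finite(vals) | vals < 0 | vals != round(vals))
  if (length(bad) > 0L) {
    abort(sprintf("malformed count at line %d: %s",
                  body_idx[bad[1L]], lines[body_idx[bad[1L]]]))
  }
  activity_trace(as.integer(vals), dt = dt,
                 meta = list(source = path, header = header))
}

parse_header_value <- function(header, key) {
  pat <- paste0("^#\\s*", key, "\\s+")
  hit <- grep(pat, header, value = TRUE)
  if (length(hit) == 0L) return(NA_real_)
  suppressWarnings(as.numeric(sub(pat, "", hit[1L])))
}

#' @rdname read_trace
#' @param provenance Optional named list written into the header as
#'   `# key value` lines.
#' @export
write_trace <- function(trace, path, provenance = NULL) {
  header <- c("# reverbkit trace v1",
              sprintf("# dt %s", format(trace_dt(trace), digits = 15)))
  prov <- provenance %||% trace_meta(trace)
  header <- c(header, format_provenance(prov))
  writeLines(c(header, as.character(trace$count)), path)
  invisible(path)
}

format_provenance <- function(prov) {
  prov <- prov[vapply(prov, function(v)
    is.atomic(v) && length(v) == 1L && !is.na(v), logical(1))]
  if (length(prov) == 0L) return(character(0))
  sprintf("# %s %s", names(prov), vapply(prov, format, character(1)))
}

#' Read and write spike-raster files
#'
#' Rasters are tab-separated `neuron<TAB>bin` event lists (1-based
#' indices) with `#` headers recording `n_neurons`, `n_bins` and `dt`.
#'
#' @param path File path.
#' @param raster A [spike_raster()].
#' @return `read_raster()` returns a [spike_raster()];
#'   `write_raster()` returns `path` invisibly.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path)
  is_header <- grepl("^#", lines)
  header <- lines[is_header]
  n_neurons <- parse_header_value(header, "n_neurons")
  n_bins <- parse_header_value(header, "n_bins")
  dt <- parse_header_value(header, "dt")
  if (anyNA(c(n_neurons, n_bins, dt))) {
    abort("raster header must carry n_neurons, n_bins and dt")
  }
  body <- lines[!is_header & nzchar(trimws(lines))]
  if (length(body) > 0L) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    ok <- lengths(parts) == 2L
    if (any(!ok)) abort(sprintf("malformed raster line: %s", body[!ok][1L]))
    neuron <- as.integer(vapply(parts, `[[`, character(1), 1L))
    bin <- as.integer(vapply(parts, `[[`, character(1), 2L))
  } else {
    neuron <- integer(0); bin <- integer(0)
  }
  spike_raster(tibble(neuron = neuron, bin = bin),
               n_neurons = n_neurons, n_bins = n_bins, dt = dt,
               meta = list(source = path, header = header))
}

#' @rdname read_raster
#' @param provenance Optional named list written into the header.
#' @export
write_raster <- function(raster, path, provenance = NULL) {
  header <- c("# reverbkit raster v1",
              sprintf("# n_neurons %d", attr(raster, "n_neurons")),
              sprintf("# n_bins %d", attr(raster, "n_bins")),
              sprintf("# dt %s", format(attr(raster, "dt"), digits = 15)),
              format_provenance(provenance %||% trace_meta(raster)))
  body <- sprintf("%d\t%d", raster$neuron, raster$bin)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a directory of aligned trial traces
#'
#' Reads every `*.txt` trace file in `dir` (sorted by name) as one trial
#' and stacks them into a long `trial_ensemble` tibble.
#'
#' @param dir Directory containing trace files written by
#'   [write_trace()].
#' @return A `trial_ensemble` tibble (columns `trial`, `bin`, `count`).
#' @export
read_trials_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (length(files) < 2L) abort("need at least 2 trial files")
  traces <- lapply(files, read_trace)
  lens <- vapply(traces, nrow, integer(1))
  if (length(unique(lens)) != 1L) abort("trial files differ in length")
  dts <- unique(vapply(traces, trace_dt, numeric(1)))
  if (length(dts) != 1L) abort("trial files differ in dt")
  new_tibble(
    list(trial = rep(seq_along(files), each = lens[1L]),
         bin = rep(seq_len(lens[1L]), times = length(files)),
         count = unlist(lapply(traces, function(tr) tr$count))),
    dt = dts, meta = list(source = dir), class = "trial_ensemble"
  )
}

#' Generate the canonical synthetic fixture set
#'
#' Writes small, fully synthetic reference data spanning the dynamical
#' regimes: traces at `m` in {0, 0.9, 0.98, 0.999} with the drive `h`
#' chosen as `h = r0 * (1 - m)` so all regimes share the same stationary
#' rate `r0`; one 50-neuron raster per regime; a trial ensemble with a
#' mid-trial efficacy switch; and a `manifest.csv` recording the ground
#' truth for every file.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed; sub-seeds per file are derived from it.
#' @param r0 Common stationary rate of the fixture traces (spikes/bin).
#' @param n_bins Trace length in bins.
#' @param dt Bin width (ms).
#' @return The manifest tibble, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 1, r0 = 100, n_bins = 1e4, dt = 4) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ms <- c(0, 0.9, 0.98, 0.999)
  rows <- list()
  for (i in seq_along(ms)) {
    m <- ms[i]
    h <- r0 * (1 - m)
    f <- file.path(out_dir, sprintf("trace_m%s.txt", sub("^0\\.", "", format(m))))
    tr <- simulate_branching(m = m, h = h, n_bins = n_bins, dt = dt,
                             seed = seed + 100L * i)
    write_trace(tr, f, provenance = list(kind = "fixture", m = m, h = h,
                                         seed = seed + 100L * i))
    rows[[length(rows) + 1L]] <- tibble(file = basename(f), kind = "trace",
                                        m = m, h = h, n_bins = n_bins, dt = dt,
                                        seed = seed + 100L * i)
    rf <- file.path(out_dir, sprintf("raster_m%s.txt", sub("^0\\.", "", format(m))))
    ra <- simulate_raster(m = m, h = 10 * (1 - m) + 1e-12, n_bins = 2000,
                          n_neurons = 50, dt = dt, seed = seed + 100L * i + 1L)
    write_raster(ra, rf, provenance = list(kind = "fixture", m = m,
                                           seed = seed + 100L * i + 1L))
    rows[[length(rows) + 1L]] <- tibble(file = basename(rf), kind = "raster",
                                        m = m, h = 10 * (1 - m), n_bins = 2000,
                                        dt = dt, seed = seed + 100L * i + 1L)
  }
  # trial ensemble with an efficacy step 0.7 -> 0.95 at mid-trial
  trial_dir <- file.path(out_dir, "trials_step")
  dir.create(trial_dir, showWarnings = FALSE)
  sch <- data.frame(start_bin = c(1L, 251L), m = c(0.7, 0.95))
  ens <- simulate_trials(n_trials = 50, m = NA, h = 2, n_bins = 500, dt = dt,
                         seed = seed + 1000L, m_schedule = sch)
  for (id in unique(ens$trial)) {
    tr <- activity_trace(ens$count[ens$trial == id], dt = dt)
    write_trace(tr, file.path(trial_dir, sprintf("trial_%03d.txt", id)),
                provenance = list(kind = "fixture_trial", trial = id,
                                  m_before = 0.7, m_after = 0.95,
                                  switch_bin = 251L, h = 2))
  }
  rows[[length(rows) + 1L]] <- tibble(file = "trials_step/", kind = "trials",
                                      m = NA_real_, h = 2, n_bins = 500, dt = dt,
                                      seed = seed + 1000L)
  manifest <- bind_rows(rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
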