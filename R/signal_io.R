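BEND_CHANNELS <- c("thumb", "index", "middle", "ring", "little")
ACCEL_CHANNELS <- c("ax", "ay", "az")

#' Multichannel glove recording
#'
#' A `recording` bundles one block of sensor data from the glove: finger bend
#' angles (degrees), palm/finger pressures (force units) or triaxial
#' accelerations (g), together with the sampling frequency and free-form
#' metadata (subject id, gesture or action name, label).  Time is implicit:
#' sample `i` occurs at `(i - 1) / fs` seconds.
#'
#' @param data numeric matrix, samples in rows, channels in columns.  A
#'   vector is treated as a single channel; a data frame is coerced.
#' @param kind one of `"bend"`, `"pressure"`, `"accel"`.
#' @param fs sampling frequency in Hz (> 0).
#' @param channels channel names; defaults depend on `kind`
#'   (`thumb`..`little` for bend, `ax, ay, az` for accel).
#' @param units measurement units; defaults depend on `kind`.
#' @param meta named list of free-form metadata.
#' @param accel_range acquisition range in g used to validate accelerometer
#'   samples (default 4).
#'
#' @details Invariants enforced at construction: at least one sample; `fs > 0`;
#'   accelerometer recordings have exactly the three channels `ax, ay, az`
#'   with all values within `accel_range`; bend recordings have exactly five
#'   finger channels with angles in \[0, 180\] degrees.
#'
#' @return an object of class `recording`.
#' @export
#' @examples
#' r <- recording(matrix(rnorm(300, sd = 0.01), ncol = 3), kind = "accel", fs = 100)
#' r$fs
recording <- function(data, kind = c("bend", "pressure", "accel"), fs = 100,
                      channels = NULL, units = NULL, meta = list(),
                      accel_range = 4) {
  kind <- match.arg(kind)
  if (is.data.frame(data)) data <- as.matrix(data)
  if (is.vector(data)) data <- matrix(data, ncol = 1)
  storage.mode(data) <- "double"
  if (nrow(data) < 1L) stop("recording must contain at least one sample")
  if (!all(is.finite(data))) stop("recording data must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar (Hz)")

  if (kind == "accel" && ncol(data) != 3L)
    stop("accel recordings must have exactly the 3 channels ax, ay, az")
  if (kind == "bend" && ncol(data) != 5L)
    stop("bend recordings must have exactly 5 finger channels")
  if (is.null(channels)) {
    channels <- switch(kind,
      accel = ACCEL_CHANNELS,
      bend = BEND_CHANNELS,
      pressure = colnames(data) %||% paste0("region", seq_len(ncol(data))))
  }
  if (length(channels) != ncol(data))
    stop(sprintf("expected %d channel names, got %d", ncol(data), length(channels)))
  if (is.null(units))
    units <- switch(kind, bend = "degrees", pressure = "force units", accel = "g")

  if (kind == "accel") {
    if (!identical(channels, ACCEL_CHANNELS))
      stop("accel recordings must have exactly the 3 channels ax, ay, az")
    if (any(abs(data) > accel_range))
      stop(sprintf("acceleration outside the +/-%g g acquisition range", accel_range))
  }
  if (kind == "bend" && any(data < 0 | data > 180))
    stop("bend angles must lie in [0, 180] degrees")
  colnames(data) <- channels
  structure(list(kind = kind, channels = channels, data = data, fs = fs,
                 units = units, meta = meta),
            class = "recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> kind=%s  %d samples x %d channels  fs=%g Hz  [%s]\n",
              x$kind, nrow(x$data), ncol(x$data), x$fs, x$units))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.recording <- function(x) dim(x$data)

#' Run configuration
#'
#' Bundles every tunable parameter of the assessment pipeline with the
#' defaults used throughout: 100 Hz sampling, +/-4 g accelerometer range,
#' 3--8 Hz tremor band, median window 5, EWA smoothing factor 0.2, equal-width
#' flexibility thresholds, six strength clusters, 8:2 train/test split and
#' tenfold cross-validation.
#'
#' @param fs sampling frequency in Hz.
#' @param accel_range accelerometer acquisition range in g.
#' @param band two-element numeric, bandpass corner frequencies in Hz.
#' @param median_window odd integer, median-filter window length.
#' @param ewa_alpha smoothing factor of the exponentially weighted average,
#'   in (0, 1].
#' @param seed integer seed governing every stochastic step.
#' @param grade_thresholds four increasing cut points on the normalised
#'   maximum bend partitioning \[0, 1\] into the five F grades.
#' @param kmeans_k number of strength clusters (Lovett scale: 6).
#' @param split_ratio training fraction of the train/test split.
#' @param cv_folds number of cross-validation folds.
#' @param include_fused_freq logical; if `TRUE` the fused-signal dominant
#'   frequency replaces nothing but is appended as a tenth feature (the
#'   default nine-feature vector excludes it).
#' @param log_eps offset used inside logarithmic features, in g.
#'
#' @return a named list of class `run_config`.
#' @export
run_config <- function(fs = 100, accel_range = 4, band = c(3, 8),
                       median_window = 5, ewa_alpha = 0.2, seed = 1L,
                       grade_thresholds = c(0.2, 0.4, 0.6, 0.8),
                       kmeans_k = 6, split_ratio = 0.8, cv_folds = 10,
                       include_fused_freq = FALSE, log_eps = 1e-6) {
  stopifnot(length(band) == 2L)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < fs / 2))
    stop("band must satisfy 0 < low < high < fs/2")
  if (median_window %% 2 != 1 || median_window < 1)
    stop("median_window must be an odd integer >= 1")
  if (ewa_alpha <= 0 || ewa_alpha > 1) stop("ewa_alpha must lie in (0, 1]")
  if (!all(diff(grade_thresholds) > 0) || length(grade_thresholds) != 4L)
    stop("grade_thresholds must be 4 strictly increasing cut points")
  structure(list(fs = fs, accel_range = accel_range, band = band,
                 median_window = as.integer(median_window),
                 ewa_alpha = ewa_alpha, seed = as.integer(seed),
                 grade_thresholds = grade_thresholds,
                 kmeans_k = as.integer(kmeans_k), split_ratio = split_ratio,
                 cv_folds = as.integer(cv_folds),
                 include_fused_freq = include_fused_freq, log_eps = log_eps),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path YAML file whose top-level keys mirror [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  bad <- setdiff(names(vals), allowed)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Write a recording to CSV
#'
#' The file starts with `#`-prefixed metadata lines (`kind`, `fs`, `units`
#' and every `meta` entry), then a header row of channel names, then the
#' numeric samples.  Values are written with enough digits for a lossless
#' round trip (at least 9 significant digits).
#'
#' @param rec a `recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  if (ncol(rec$data) == 0L) stop("cannot write a recording with no channels")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# kind: %s", rec$kind), con)
  writeLines(sprintf("# fs: %s", format(rec$fs, digits = 15)), con)
  writeLines(sprintf("# units: %s", rec$units), con)
  for (key in names(rec$meta))
    writeLines(sprintf("# meta.%s: %s", key, as.character(rec$meta[[key]])), con)
  writeLines(paste(rec$channels, collapse = ","), con)
  body <- apply(rec$data, 1L, function(row)
    paste(formatC(row, digits = 12, format = "g"), collapse = ","))
  writeLines(body, con)
  invisible(path)
}

#' Read a recording from CSV
#'
#' Parses the `#` metadata block written by [write_recording()]; `kind`,
#' `fs` and `units` found there override the arguments.  The recording is
#' validated on construction (channel counts, accelerometer range, bend
#' angle range).
#'
#' @param path CSV file path.
#' @param kind expected recording kind; overridden by an embedded
#'   `# kind:` line.
#' @param fs fallback sampling frequency when the file carries none.
#' @param accel_range acquisition range used for validation.
#' @return a `recording`.
#' @export
read_recording <- function(path, kind = c("bend", "pressure", "accel"),
                           fs = 100, accel_range = 4) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- grepl("^#", lines)
  n_meta <- match(FALSE, is_meta, nomatch = length(lines) + 1L) - 1L
  meta_lines <- lines[seq_len(n_meta)]
  meta <- list()
  units <- NULL
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([A-Za-z0-9_.]+):\\s*(.*)$", ml))[[1]]
    if (length(m) != 3L) next
    key <- m[2]; val <- m[3]
    if (key == "kind") kind <- val
    else if (key == "fs") fs <- as.numeric(val)
    else if (key == "units") units <- val
    else if (startsWith(key, "meta.")) {
      v <- suppressWarnings(as.numeric(val))
      meta[[substring(key, 6)]] <- if (!is.na(v) && grepl("^[-0-9.eE+]+$", val)) v else val
    }
  }
  body <- lines[(n_meta + 1L):length(lines)]
  if (length(body) < 2L) stop("malformed CSV (no data rows): ", path)
  channels <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  widths <- lengths(rows)
  if (any(widths != length(channels)))
    stop(sprintf("malformed CSV row %d in %s: expected %d fields, got %d",
                 which(widths != length(channels))[1] + 1L, path,
                 length(channels), widths[widths != length(channels)][1]))
  mat <- matrix(suppressWarnings(as.numeric(unlist(rows))),
                ncol = length(channels), byrow = TRUE)
  if (anyNA(mat)) {
    bad <- which(rowSums(is.na(mat)) > 0)[1]
    stop(sprintf("non-numeric value in data row %d of %s", bad, path))
  }
  recording(mat, kind = kind, fs = fs, channels = channels, units = units,
            meta = meta, accel_range = accel_range)
}
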