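GESTURES <- c("Flat hand", "Fist", "OK", "Orchid fingers",
              "A", "W", "B", "U", "V")

F_GRADES <- paste0("F", 0:4)

#' Min-max normalisation of bend angles
#'
#' Maps angles from \[`lo`, `hi`\] degrees onto \[0, 1\] by
#' `(x - lo) / (hi - lo)`, clipping to the unit interval.  Removes the
#' physical dimension so that grading thresholds are subject-independent.
#'
#' @param x numeric angles in degrees.
#' @param lo,hi calibration range, `lo < hi` (defaults 0 and 180).
#' @return values in \[0, 1\].
#' @export
#' @examples
#' minmax_normalize(c(0, 90, 180))  # 0, 0.5, 1
minmax_normalize <- function(x, lo = 0, hi = 180) {
  if (lo >= hi) stop("lo must be strictly less than hi")
  pmin(pmax((x - lo) / (hi - lo), 0), 1)
}

#' Flexibility grade from normalised maximum bend
#'
#' Assigns one of the five grades F0 (worst) .. F4 (best), a refinement of
#' the four-grade TAM range-of-motion standard.  The four cut points
#' partition \[0, 1\] into five half-open bins `[a, b)`; a value exactly on
#' a cut point falls in the upper bin, and 1 is F4.
#'
#' @param max_norm normalised maximum bend in \[0, 1\].
#' @param thresholds four strictly increasing cut points (default
#'   `c(0.2, 0.4, 0.6, 0.8)`, equal-width bins).
#' @return a factor with levels `F0`..`F4`.
#' @export
grade_flexibility <- function(max_norm, thresholds = c(0.2, 0.4, 0.6, 0.8)) {
  if (length(thresholds) != 4L || !all(diff(thresholds) > 0))
    stop("thresholds must be 4 strictly increasing cut points")
  if (any(max_norm < 0 | max_norm > 1)) stop("max_norm must lie in [0, 1]")
  idx <- findInterval(max_norm, thresholds, left.open = FALSE) # [a, b) bins
  factor(F_GRADES[idx + 1L], levels = F_GRADES)
}

#' Assess finger flexibility from gesture recordings
#'
#' Each bend recording (one per gesture, optionally repeated) is smoothed
#' per finger with the EWA filter, min-max normalised, and reduced to its
#' per-finger maximum.  Grading uses the maximum over all gestures,
#' repetitions and fingers: the best flexion the subject can produce.
#' Extension gestures such as "Flat hand" contribute their residual bend to
#' the logged per-gesture maxima but flexion range drives the grade.
#'
#' @param recordings list of bend `recording`s; `meta$gesture` names the
#'   gesture (unknown names produce a warning and are still processed).
#' @param config a [run_config()].
#' @return an object of class `flexibility_result`: list with
#'   `per_finger_norm` (5 values), `max_norm`, `grade`, `gesture_set` and
#'   `per_gesture_max`.
#' @export
assess_flexibility <- function(recordings, config = run_config()) {
  if (length(recordings) < 1L) stop("need at least one gesture recording")
  per_finger <- matrix(0, nrow = length(recordings), ncol = 5L,
                       dimnames = list(NULL, BEND_CHANNELS))
  gestures <- character(length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    stopifnot(inherits(rec, "recording"))
    if (rec$kind != "bend") stop("assess_flexibility expects bend recordings")
    g <- rec$meta$gesture %||% "unknown"
    if (!g %in% GESTURES)
      warning("unknown gesture name: ", g, " (processed anyway)")
    gestures[i] <- g
    filt <- apply(rec$data, 2L, ewa_filter, alpha = config$ewa_alpha)
    per_finger[i, ] <- apply(minmax_normalize(filt), 2L, max)
  }
  per_finger_norm <- apply(per_finger, 2L, max)
  max_norm <- max(per_finger_norm)
  structure(list(per_finger_norm = per_finger_norm,
                 max_norm = max_norm,
                 grade = grade_flexibility(max_norm, config$grade_thresholds),
                 gesture_set = unique(gestures),
                 per_gesture_max = stats::setNames(apply(per_finger, 1L, max),
                                                   gestures)),
            class = "flexibility_result")
}

#' @export
print.flexibility_result <- function(x, ...) {
  cat(sprintf("<flexibility> grade %s  max_norm=%.3f\n",
              as.character(x$grade), x$max_norm))
  cat("  per finger:", paste(sprintf("%s=%.2f", names(x$per_finger_norm),
                                     x$per_finger_norm), collapse = " "), "\n")
  invisible(x)
}
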