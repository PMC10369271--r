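FEATURE_NAMES <- c("p2p", "log_p2p", "sd", "log_sd", "rms", "log_rms",
                   "freq_x", "freq_y", "freq_z")

#' Combined (fused) acceleration
#'
#' Per-sample Euclidean norm of the three accelerometer axes,
#' `a(k) = sqrt(ax(k)^2 + ay(k)^2 + az(k)^2)`.  Fusing the triaxial signal
#' into one non-negative indicator makes tremor magnitude independent of
#' hand orientation; it is invariant under axis permutation and sign flips.
#'
#' @param ax,ay,az equal-length numeric vectors (g).
#' @return non-negative numeric vector of the same length.
#' @export
#' @examples
#' combined_acceleration(3, 4, 0)  # 5
combined_acceleration <- function(ax, ay, az) {
  if (length(ax) != length(ay) || length(ay) != length(az))
    stop("axis signals must have equal length")
  if (length(ax) < 1L) stop("empty signal")
  sqrt(ax^2 + ay^2 + az^2)
}

#' Dominant frequency within a band
#'
#' Frequency of the maximum-magnitude DFT bin restricted to
#' \[`low`, `high`\] Hz, after removing the mean and applying a Hann window.
#' With a 5 s window at 100 Hz the bin width is 0.2 Hz.  No interpolation
#' between bins is performed.
#'
#' @param x numeric vector, at least 1 s long (`length(x) >= fs`).
#' @param fs sampling frequency in Hz.
#' @param band two-element numeric, search band in Hz.
#' @return dominant frequency in Hz.
#' @export
dominant_frequency <- function(x, fs = 100, band = c(3, 8)) {
  n <- length(x)
  if (n < fs) stop("need at least one second of signal")
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))  # Hann
  spec <- Mod(stats::fft((x - mean(x)) * w))
  freqs <- (seq_len(n) - 1L) * fs / n
  keep <- freqs >= band[1] & freqs <= band[2] & freqs <= fs / 2
  if (!any(keep)) stop("band empty after restriction to DFT bins")
  freqs[keep][which.max(spec[keep])]
}

#' Nine-element tremor feature vector
#'
#' Runs each acceleration axis through the tremor preprocessing chain
#' (median filter, 3--8 Hz zero-phase bandpass, adaptive Kalman), fuses the
#' axes into the combined acceleration, and extracts six time-domain
#' features of the fused signal -- peak-to-peak, standard deviation, RMS
#' and their logarithms `ln(x + eps)` -- plus the dominant frequency of each
#' filtered axis.  The fused-signal dominant frequency is appended as a
#' tenth element when `config$include_fused_freq` is `TRUE`; the default
#' nine-element vector matches the classifier's nine input nodes.
#'
#' @param rec a 3-channel accelerometer `recording` at least 1 s long.
#' @param config a [run_config()].
#' @return named numeric vector of length 9 (or 10), class `feature_vector`.
#' @export
extract_features <- function(rec, config = run_config()) {
  stopifnot(inherits(rec, "recording"))
  if (rec$kind != "accel") stop("extract_features expects an accel recording")
  if (nrow(rec$data) < config$fs) stop("recording shorter than 1 s")
  filt <- apply(rec$data, 2L, preprocess_tremor_axis, config = config)
  fused <- combined_acceleration(filt[, 1], filt[, 2], filt[, 3])
  eps <- config$log_eps
  p2p <- max(fused) - min(fused)
  sdv <- stats::sd(fused)
  rms <- sqrt(mean(fused^2))
  freqs <- apply(filt, 2L, dominant_frequency, fs = config$fs,
                 band = config$band)
  out <- c(p2p = p2p, log_p2p = log(p2p + eps),
           sd = sdv, log_sd = log(sdv + eps),
           rms = rms, log_rms = log(rms + eps),
           freq_x = unname(freqs[1]), freq_y = unname(freqs[2]),
           freq_z = unname(freqs[3]))
  if (isTRUE(config$include_fused_freq))
    out <- c(out, freq_fused = dominant_frequency(fused, fs = config$fs,
                                                  band = config$band))
  structure(out, class = c("feature_vector", "numeric"))
}
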