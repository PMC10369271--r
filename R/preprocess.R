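#' Exponentially weighted average filter
#'
#' First-order recursive smoother `y[t] = alpha * x[t] + (1 - alpha) * y[t-1]`
#' with `y[1] = x[1]`, used to suppress environmental disturbance on the slow
#' bend and pressure channels.  Every output sample is a convex combination
#' of past inputs, so the output stays within `range(x)`.
#'
#' @param x numeric vector, length >= 1.
#' @param alpha smoothing factor in (0, 1]; `alpha = 1` is the identity.
#' @return filtered vector of the same length.
#' @export
#' @examples
#' ewa_filter(c(0, 1, 1, 1), alpha = 0.5)  # 0, 0.5, 0.75, 0.875
ewa_filter <- function(x, alpha = 0.2) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  n <- length(x)
  if (n < 1L) stop("empty signal")
  y <- numeric(n)
  y[1] <- x[1]
  if (n > 1L) {
    z <- as.numeric(stats::filter(alpha * x[-1], 1 - alpha,
                                  method = "recursive", init = x[1]))
    y[-1] <- z
  }
  y
}

#' Centred sliding median filter
#'
#' Replaces each sample by the median of the window centred on it.  Edges
#' are handled by edge replication: the first and last samples are repeated
#' `(window - 1) / 2` times before filtering, so the output has the same
#' length as the input and no zeros are introduced at the borders.
#'
#' @param x numeric vector.
#' @param window odd integer window length, `<= length(x)`.
#' @return filtered vector of the same length.
#' @export
median_filter <- function(x, window = 5) {
  window <- as.integer(window)
  if (window %% 2L != 1L || window < 1L) stop("window must be an odd integer >= 1")
  n <- length(x)
  if (window > n) stop("window longer than signal")
  if (window == 1L) return(x)
  h <- (window - 1L) %/% 2L
  padded <- c(rep(x[1], h), x, rep(x[n], h))
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- stats::median(padded[i:(i + window - 1L)])
  out
}

#' Zero-phase Butterworth bandpass filter
#'
#' 4th-order Butterworth bandpass applied forward and backward
#' (`signal::filtfilt`), giving zero phase distortion so tremor peaks are
#' not shifted in time.  Defaults isolate the 3--8 Hz static-tremor band,
#' removing drift (temperature, gravity orientation) below and powerline /
#' sensor noise above.
#'
#' @param x numeric vector, longer than three times the filter order.
#' @param fs sampling frequency in Hz.
#' @param low,high corner frequencies in Hz, `0 < low < high < fs/2`.
#' @param order filter order (default 4).
#' @return filtered vector of the same length.
#' @export
bandpass_filter <- function(x, fs = 100, low = 3, high = 8, order = 4) {
  if (!(low > 0 && low < high && high < fs / 2))
    stop("need 0 < low < high < fs/2")
  if (length(x) < 3 * order) stop("signal too short for the filter order")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  # remove the DC component first: the passband rejects it anyway, and a
  # large offset (e.g. gravity on the z axis) otherwise leaks into the
  # forward-backward initial conditions as an edge transient
  as.numeric(signal::filtfilt(bf, x - mean(x)))
}

#' Adaptive scalar Kalman filter
#'
#' Scalar local-level Kalman filter: the state is the underlying signal
#' level, modelled as a random walk with process noise `Q`, observed with
#' measurement noise `R`.  When `adapt = TRUE` (the default) both noise
#' variances are re-estimated at every step from the trailing window:
#' the measurement noise from a robust (median absolute deviation) estimate
#' of the first-difference sequence, `R <- (mad(diff(x)) / 0.6745)^2 / 2`,
#' which white noise dominates; and the process noise from the innovation
#' consistency condition `E[innovation^2] = P + Q + R`, i.e.
#' `Q <- max(C - P - R, floor)` with `C` the windowed mean squared
#' innovation.  Attributing excess innovation to the process (not the
#' measurement) keeps the gain high while the underlying level is genuinely
#' moving -- a tremor oscillation passes nearly unattenuated -- and lets it
#' fall when the innovations are pure noise, which is then smoothed away.
#' With `adapt = FALSE` the recursion is the textbook constant Q/R scalar
#' Kalman filter.
#'
#' @param x numeric vector.
#' @param Q initial process-noise variance (> 0).
#' @param R initial measurement-noise variance (> 0).
#' @param P0 initial estimate variance (>= 0).
#' @param x0 initial state estimate; defaults to the first sample.
#' @param window trailing window length for innovation statistics.
#' @param adapt logical, enable noise adaptation.
#' @return filtered vector of the same length.
#' @export
kalman_filter <- function(x, Q = 1e-4, R = 1e-2, P0 = 1, x0 = x[1],
                          window = 50, adapt = TRUE) {
  if (Q <= 0 || R <= 0) stop("initial Q and R must be positive")
  if (P0 < 0) stop("P0 must be non-negative")
  n <- length(x)
  if (adapt && n < window)
    stop("signal shorter than the adaptation window")
  floor_var <- 1e-12
  y <- numeric(n)
  innov <- numeric(n)
  xhat <- x0
  P <- P0
  for (k in seq_len(n)) {
    x_pred <- xhat          # random-walk prediction
    P_pred <- P + Q
    d <- x[k] - x_pred      # innovation
    innov[k] <- d
    K <- P_pred / (P_pred + R)
    xhat <- x_pred + K * d
    P <- (1 - K) * P_pred
    y[k] <- xhat
    if (adapt && k >= window) {
      w <- (k - window + 1L):k
      C <- mean(innov[w]^2)
      dx <- diff(x[w])
      R <- max((stats::median(abs(dx)) / 0.6745)^2 / 2, floor_var)
      Q <- max(C - P - R, floor_var)
    }
  }
  y
}

#' Tremor preprocessing chain
#'
#' Applies, in order, the median filter, the 3--8 Hz zero-phase bandpass and
#' the adaptive Kalman filter to one acceleration axis.
#'
#' @param x numeric vector (one acceleration axis, g).
#' @param config a [run_config()].
#' @return filtered vector of the same length.
#' @export
preprocess_tremor_axis <- function(x, config = run_config()) {
  x <- median_filter(x, config$median_window)
  x <- bandpass_filter(x, fs = config$fs, low = config$band[1],
                       high = config$band[2])
  kalman_filter(x)
}
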