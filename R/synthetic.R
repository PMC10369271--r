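# Per-finger flexion targets as fractions of full (180 degree) flexion for
# the nine assessment gestures; 0 = fully extended.  Fingers: thumb, index,
# middle, ring, little.
GESTURE_TEMPLATES <- list(
  "Flat hand"      = c(0.00, 0.00, 0.00, 0.00, 0.00),
  "Fist"           = c(1.00, 1.00, 1.00, 1.00, 1.00),
  "OK"             = c(0.80, 0.80, 0.10, 0.10, 0.10),
  "Orchid fingers" = c(0.60, 0.20, 0.60, 0.25, 0.20),
  "A"              = c(0.30, 1.00, 1.00, 1.00, 1.00),
  "W"              = c(0.80, 0.05, 0.05, 0.05, 0.80),
  "B"              = c(1.00, 0.05, 0.05, 0.05, 0.05),
  "U"              = c(0.80, 0.05, 0.05, 1.00, 1.00),
  "V"              = c(0.80, 0.05, 0.05, 1.00, 1.00)
)

# Relative activation of the pressure regions per grip/pinch action.
# "Grasp the cylinder" recruits every region at full level: the action with
# the most physical contact, so a given strength produces its global force
# maximum there.
ACTION_TEMPLATES <- list(
  "Grasp the cylinder"           = c(thumb = 1.0, index = 1.0, middle = 1.0,
                                     ring = 1.0, little = 1.0, palm = 1.0,
                                     purlicue = 1.0),
  "Pinch objects with fingertip" = c(thumb = 0.85, index = 0.85, middle = 0.1,
                                     ring = 0.05, little = 0.05, palm = 0.05,
                                     purlicue = 0.4),
  "Grasp the ball"               = c(thumb = 0.9, index = 0.9, middle = 0.9,
                                     ring = 0.85, little = 0.8, palm = 0.7,
                                     purlicue = 0.5),
  "Click objects with finger"    = c(thumb = 0.1, index = 0.75, middle = 0.1,
                                     ring = 0.05, little = 0.05, palm = 0.05,
                                     purlicue = 0.1)
)

# Default amplitude range (g) of the simulated tremor per severity class.
# Class 0 is noise only; classes 1 and 2 are disjoint bands wide enough that
# the filtered features overlap only through noise.
TREMOR_AMPLITUDE <- list(`0` = c(0, 0), `1` = c(0.05, 0.25), `2` = c(0.4, 1.2))

#' Simulate an accelerometer tremor recording
#'
#' Emulates 5 s of palm-down static-posture accelerometry at 100 Hz:
#' each axis carries `gain * A * sin(2*pi*f*t + phase)` plus Gaussian noise,
#' with gravity (1 g) on the z axis.  The tremor frequency is drawn
#' uniformly from the 3--8 Hz band and the amplitude from the
#' severity-dependent range (class 0: no tremor, noise only; class 1:
#' 0.05--0.25 g; class 2: 0.4--1.2 g).  Axis gains (1.0, 0.7, 0.5) encode
#' the dominant tremor plane.  Deterministic for a given seed.
#'
#' @param severity tremor class 0, 1 or 2 (No / Mild / Severe).
#' @param seed integer seed.
#' @param fs sampling frequency in Hz (default 100).
#' @param duration recording length in seconds (default 5).
#' @param freq tremor frequency in Hz; `NULL` (default) draws uniformly
#'   from `band`.
#' @param amplitude tremor amplitude in g; `NULL` draws from the class range.
#' @param noise_sd additive noise standard deviation in g (default 0.02).
#' @param band frequency band the tremor is drawn from.
#' @param axis_gains per-axis amplitude gains.
#' @param accel_range acquisition range in g; samples are clipped to it.
#' @return an accel `recording` with `meta$label = severity`.
#' @export
simulate_tremor <- function(severity, seed = 1L, fs = 100, duration = 5,
                            freq = NULL, amplitude = NULL, noise_sd = 0.02,
                            band = c(3, 8), axis_gains = c(1.0, 0.7, 0.5),
                            accel_range = 4) {
  if (!severity %in% 0:2) stop("severity must be 0, 1 or 2")
  set.seed(seed)
  if (is.null(freq)) freq <- stats::runif(1, band[1], band[2])
  if (is.null(amplitude)) {
    rng <- TREMOR_AMPLITUDE[[as.character(severity)]]
    amplitude <- if (rng[2] > rng[1]) stats::runif(1, rng[1], rng[2]) else rng[1]
  }
  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs
  phases <- stats::runif(3, 0, 2 * pi)
  gravity <- c(0, 0, 1)
  data <- vapply(1:3, function(ax)
    axis_gains[ax] * amplitude * sin(2 * pi * freq * t + phases[ax]) +
      gravity[ax] + stats::rnorm(n, sd = noise_sd),
    numeric(n))
  data <- pmin(pmax(data, -accel_range), accel_range)
  recording(data, kind = "accel", fs = fs,
            meta = list(label = severity, freq = freq, amplitude = amplitude,
                        seed = seed),
            accel_range = accel_range)
}

#' Simulate a labelled tremor feature dataset
#'
#' Generates `n` tremor recordings with the requested class balance (each
#' from a seed derived deterministically from `seed`), runs every recording
#' through the full tremor feature extraction, and returns the feature table
#' with its labels.
#'
#' @param n number of samples (default 120).
#' @param class_balance counts per class, summing to `n`; by default the
#'   classes are as balanced as `n` allows (`c(40, 40, 40)` at the default
#'   `n`).
#' @param seed integer master seed.
#' @param config a [run_config()] used for feature extraction.
#' @return list with `features` (`n x 9` matrix) and integer `labels`.
#' @export
simulate_dataset <- function(n = 120, class_balance = NULL,
                             seed = 1L, config = run_config()) {
  if (n < 3) stop("need at least one sample per class")
  if (is.null(class_balance))
    class_balance <- diff(round(seq(0, n, length.out = 4)))
  if (sum(class_balance) != n) stop("class_balance must sum to n")
  labels <- rep(0:2, times = class_balance)
  set.seed(seed)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, n)
  features <- matrix(NA_real_, n, 9L,
                     dimnames = list(NULL, FEATURE_NAMES))
  for (i in seq_len(n)) {
    rec <- simulate_tremor(labels[i], seed = sample_seeds[i],
                           fs = config$fs, band = config$band,
                           accel_range = config$accel_range)
    features[i, ] <- extract_features(rec, config)[FEATURE_NAMES]
  }
  list(features = features, labels = labels)
}

#' Simulate a bend recording for one gesture
#'
#' Per-finger target angles come from the built-in gesture template, capped
#' at the subject's flexion ceiling `ability * 180` degrees.  The movement
#' follows a trapezoidal ramp (1 s rise, 3 s hold, 1 s release) with
#' Gaussian noise (sd 2 degrees), clipped to \[0, 180\].
#'
#' @param gesture one of the nine gesture names (see `names of
#'   GESTURE_TEMPLATES`: "Flat hand", "Fist", "OK", "Orchid fingers", "A",
#'   "W", "B", "U", "V").
#' @param ability flexion ability in \[0, 1\]; 1 = full range.
#' @param seed integer seed.
#' @param fs sampling frequency in Hz (default 100).
#' @param duration recording length in seconds (default 5).
#' @param noise_sd angle noise in degrees (default 2).
#' @return a bend `recording` with `meta$gesture`.
#' @export
simulate_gesture_bend <- function(gesture, ability = 1, seed = 1L, fs = 100,
                                  duration = 5, noise_sd = 2) {
  tmpl <- GESTURE_TEMPLATES[[gesture]]
  if (is.null(tmpl)) stop("unknown gesture: ", gesture)
  if (ability < 0 || ability > 1) stop("ability must lie in [0, 1]")
  set.seed(seed)
  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs
  ramp <- pmin(pmin(t / 1, 1), pmin((duration - t) / 1, 1))
  ramp <- pmax(ramp, 0)
  targets <- pmin(tmpl * 180, ability * 180)
  data <- vapply(targets, function(a)
    pmin(pmax(a * ramp + stats::rnorm(n, sd = noise_sd), 0), 180),
    numeric(n))
  recording(data, kind = "bend", fs = fs,
            meta = list(gesture = gesture, ability = ability, seed = seed))
}

#' Simulate a pressure recording for one action
#'
#' Seven force regions (five fingers, palm, purlicue) receive a train of
#' three 1 s force pulses whose peak is `10 * strength_level` force units
#' scaled by the action's region-activation pattern; "Grasp the cylinder"
#' activates every region fully, so it carries the global maximum for a
#' given strength.  Gaussian noise is added and forces are clipped at zero.
#'
#' @param action one of the four action names ("Grasp the cylinder",
#'   "Pinch objects with fingertip", "Grasp the ball",
#'   "Click objects with finger").
#' @param strength_level integer 0 (no force) .. 5 (normal strength).
#' @param seed integer seed.
#' @param fs sampling frequency in Hz (default 100).
#' @param duration recording length in seconds (default 5).
#' @param unit_force peak force per strength level (default 10).
#' @param noise_sd force noise (default 0.2).
#' @return a pressure `recording` with `meta$action`.
#' @export
simulate_action_pressure <- function(action, strength_level, seed = 1L,
                                     fs = 100, duration = 5, unit_force = 10,
                                     noise_sd = 0.2) {
  tmpl <- ACTION_TEMPLATES[[action]]
  if (is.null(tmpl)) stop("unknown action: ", action)
  if (!strength_level %in% 0:5) stop("strength_level must be an integer in 0..5")
  set.seed(seed)
  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs
  # three 1 s raised-cosine pulses centred at 1, 2.5 and 4 s
  pulse <- rowSums(vapply(c(1, 2.5, 4), function(c0) {
    u <- pmax(1 - abs(t - c0) / 0.5, 0)
    0.5 - 0.5 * cos(pi * pmin(u * 2, 1))  # smooth rise to 1 at the centre
  }, numeric(n)))
  peak <- unit_force * strength_level
  data <- vapply(tmpl, function(g)
    pmax(g * peak * pulse + stats::rnorm(n, sd = noise_sd), 0),
    numeric(n))
  recording(data, kind = "pressure", fs = fs, channels = names(tmpl),
            meta = list(action = action, strength_level = strength_level,
                        seed = seed))
}

#' Simulate a population of muscle-strength maxima
#'
#' Draws maximum-force values for subjects spanning the six Lovett strength
#' levels: level `l` contributes values around `10 * l` force units with the
#' given spread.  Used to fit the population [kmeans_fit()] interval model.
#'
#' @param n_per_level subjects per strength level (default 10).
#' @param sd within-level spread (default 1.5).
#' @param seed integer seed.
#' @return numeric vector of `6 * n_per_level` non-negative force maxima.
#' @export
simulate_strength_population <- function(n_per_level = 10, sd = 1.5,
                                         seed = 1L) {
  set.seed(seed)
  vals <- unlist(lapply(0:5, function(l)
    stats::rnorm(n_per_level, mean = 10 * l, sd = sd)))
  pmax(vals, 0)
}
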