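test_that("EWA filter matches its closed form and convexity contract", {
  # unit step: y[t] = 1 - (1-alpha)^t starting from y[1] = x[1] = 1... the
  # step enters at t = 1, so with alpha = 0.5, y[t] = 1 - 0.5^t
  step <- rep(1, 20)
  y <- ewa_filter(step, alpha = 0.5)
  expect_equal(y, rep(1, 20))  # constant series is a fixed point

  # step from 0: x = (0, 1, 1, ...) gives y[t] = 1 - 0.5^(t-1)
  x <- c(0, rep(1, 19))
  y <- ewa_filter(x, alpha = 0.5)
  expect_equal(y, 1 - 0.5^(seq_along(x) - 1))

  expect_equal(ewa_filter(x, alpha = 1), x)  # identity at alpha = 1

  # direct recursion oracle on random input
  set.seed(3)
  z <- rnorm(100)
  ref <- numeric(100); ref[1] <- z[1]
  for (t in 2:100) ref[t] <- 0.3 * z[t] + 0.7 * ref[t - 1]
  expect_equal(ewa_filter(z, 0.3), ref, tolerance = 1e-12)

  # convex-combination property: output bounded by input range
  for (alpha in c(0.1, 0.5, 0.9)) {
    y <- ewa_filter(z, alpha)
    expect_true(all(y >= min(z) - 1e-12 & y <= max(z) + 1e-12))
  }
  expect_error(ewa_filter(z, 1.5), "alpha")
  expect_error(ewa_filter(z, 0), "alpha")
})

test_that("median filter equals the per-window sort oracle and removes spikes", {
  mono <- 1:20
  expect_equal(median_filter(mono, 5)[3:18], 3:18)  # interior unchanged

  spike <- rep(2, 30); spike[15] <- 100
  expect_equal(median_filter(spike, 5), rep(2, 30))

  set.seed(7)
  for (w in c(3, 5, 9)) {
    x <- rnorm(60)
    expect_equal(median_filter(x, w), bruteforce_median(x, w),
                 tolerance = 1e-12)
  }
  expect_error(median_filter(rnorm(10), 4), "odd")
  expect_error(median_filter(rnorm(3), 5), "window longer")
})

test_that("bandpass filter passes 5 Hz nearly unchanged and rejects drift", {
  fs <- 100
  t <- (0:999) / fs
  s5 <- sin(2 * pi * 5 * t)
  y <- bandpass_filter(s5, fs, 3, 8)
  core <- 201:800  # discard transients
  amp <- fit_sinusoid_amplitude(y[core], 5, fs)
  expect_gt(amp, 0.95)
  expect_lt(amp, 1.05)

  drift <- sin(2 * pi * 0.5 * t)
  yd <- bandpass_filter(drift, fs, 3, 8)
  expect_lt(sqrt(mean(yd^2)), 0.05 * sqrt(mean(drift^2)))

  expect_equal(bandpass_filter(rep(0, 500), fs, 3, 8), rep(0, 500))
  expect_error(bandpass_filter(s5, fs, 8, 3), "low < high")
  expect_error(bandpass_filter(s5, fs, 3, 60), "low < high")
})

test_that("Kalman filter matches the textbook recursion with adaptation off", {
  set.seed(21)
  z <- cumsum(rnorm(300, sd = 0.1)) + rnorm(300, sd = 0.5)
  ours <- kalman_filter(z, Q = 0.01, R = 0.25, P0 = 1, adapt = FALSE)
  ref <- textbook_kalman(z, Q = 0.01, R = 0.25, P0 = 1, x0 = z[1])
  expect_equal(ours, ref, tolerance = 1e-12)
  expect_error(kalman_filter(z, Q = 0), "positive")
  expect_error(kalman_filter(z, R = -1), "positive")
})

test_that("Kalman filter converges on constants and denoises a sinusoid", {
  y <- kalman_filter(rep(3, 200), adapt = FALSE)
  expect_lt(abs(y[100] - 3), 1e-6)
  y2 <- kalman_filter(rep(3, 200), adapt = TRUE)
  expect_lt(abs(y2[200] - 3), 1e-6)

  rmse <- function(a, b) sqrt(mean((a - b)^2))
  t <- (0:499) / 100
  # the model regime: a slowly drifting level under measurement noise
  set.seed(5)
  level <- 0.5 * sin(2 * pi * 0.3 * t)
  noisy_level <- level + rnorm(500, sd = 0.2)
  expect_lt(rmse(kalman_filter(noisy_level), level),
            rmse(noisy_level, level))
  # a 5 Hz tremor oscillation buried in heavy noise: smoothing still wins
  set.seed(5)
  clean <- sin(2 * pi * 5 * t)
  noisy <- clean + rnorm(500, sd = 0.5)
  expect_lt(rmse(kalman_filter(noisy), clean), rmse(noisy, clean))
})

test_that("all filters preserve length and map zero to zero", {
  n <- 256
  zero <- rep(0, n)
  set.seed(9)
  x <- rnorm(n)
  expect_length(ewa_filter(x, 0.4), n)
  expect_length(median_filter(x, 5), n)
  expect_length(bandpass_filter(x), n)
  expect_length(kalman_filter(x), n)
  expect_equal(ewa_filter(zero, 0.4), zero)
  expect_equal(median_filter(zero, 5), zero)
  expect_equal(bandpass_filter(zero), zero)
  expect_equal(kalman_filter(zero), zero)
})
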