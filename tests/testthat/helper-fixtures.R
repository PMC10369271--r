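# Shared fixtures and independent oracles used across the suite.

# Rater tables reconstructed from the printed grade shares and single
# disagreements of the three clinical agreement analyses (rows = system,
# cols = clinician).
flexibility_table <- function() {
  matrix(c(2, 0, 0,
           1, 1, 0,
           0, 0, 8), 3, byrow = TRUE,
         dimnames = list(c("F2", "F3", "F4"), c("F2", "F3", "F4")))
}

strength_table <- function() {
  matrix(c(1, 0, 0, 0,
           0, 3, 0, 0,
           0, 0, 6, 0,
           0, 0, 1, 1), 4, byrow = TRUE,
         dimnames = list(c("M0", "M2", "M4", "M5"), c("M0", "M2", "M4", "M5")))
}

stability_confusion <- function() {
  matrix(c(8, 0, 0,
           0, 9, 1,
           0, 0, 6), 3, byrow = TRUE)
}

# Textbook constant-gain scalar Kalman recursion, written independently of
# kalman_filter(): predict with a random walk, update with fixed Q and R.
textbook_kalman <- function(z, Q, R, P0, x0) {
  out <- numeric(length(z))
  x <- x0; P <- P0
  for (i in seq_along(z)) {
    P_prior <- P + Q
    K <- P_prior / (P_prior + R)
    x <- x + K * (z[i] - x)
    P <- (1 - K) * P_prior
    out[i] <- x
  }
  out
}

# Brute-force sliding median with edge replication.
bruteforce_median <- function(x, w) {
  h <- (w - 1) / 2
  n <- length(x)
  xp <- c(rep(x[1], h), x, rep(x[n], h))
  sapply(seq_len(n), function(i) {
    win <- sort(xp[i:(i + w - 1)])
    win[h + 1]
  })
}

# Exhaustive global 1-D k-means: minimal WCSS over every assignment of n
# points to k labels (k^n enumeration; for n <= 8, k = 2 that is 256 cases).
bruteforce_kmeans_wcss <- function(values, k) {
  n <- length(values)
  grid <- expand.grid(rep(list(seq_len(k)), n))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    if (length(unique(a)) < k) next
    wcss <- sum(sapply(seq_len(k), function(j) {
      v <- values[a == j]
      sum((v - mean(v))^2)
    }))
    best <- min(best, wcss)
  }
  best
}

# Least-squares amplitude of a sinusoid of known frequency in a series.
fit_sinusoid_amplitude <- function(x, f, fs) {
  t <- (seq_along(x) - 1) / fs
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  coef <- stats::lm.fit(X, x)$coefficients
  sqrt(sum(coef^2))
}

# Balanced subjects x measurements matrix with given between/within sds.
icc_ground_truth_data <- function(n_subj, n_meas, sd_between, sd_within, seed) {
  set.seed(seed)
  subj <- rnorm(n_subj, 0, sd_between)
  matrix(rnorm(n_subj * n_meas, rep(subj, n_meas), sd_within), n_subj, n_meas)
}

# Linearly separable 3-class feature set: classes shifted by a large margin
# on disjoint feature axes, with all 9 columns populated.
separable_features <- function(n_per_class = 20, seed = 1) {
  set.seed(seed)
  n <- 3 * n_per_class
  labels <- rep(0:2, each = n_per_class)
  base <- matrix(rnorm(n * 9, sd = 0.3), n, 9)
  base[, 1] <- base[, 1] + 6 * labels           # p2p-like axis
  base[, 5] <- base[, 5] + 4 * (labels == 2)    # rms-like axis
  colnames(base) <- c("p2p", "log_p2p", "sd", "log_sd", "rms", "log_rms",
                      "freq_x", "freq_y", "freq_z")
  list(features = base, labels = labels)
}
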