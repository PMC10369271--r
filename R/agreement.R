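kappa_band <- function(k) {
  if (k > 0.8) "excellent" else if (k > 0.6) "good"
  else if (k > 0.4) "moderate" else "poor"
}

icc_band <- function(r) {
  if (r > 0.9) "excellent" else if (r > 0.75) "good"
  else if (r > 0.5) "moderate" else "poor"
}

#' Build a rater contingency table
#'
#' Cross-tabulates two vectors of categorical grades (system vs clinician)
#' over the union of their levels, returning a square counts matrix suitable
#' for [cohen_kappa()].
#'
#' @param rater_a,rater_b equal-length vectors of grades (system in rows,
#'   clinician in columns).
#' @param levels optional explicit category ordering.
#' @return square integer matrix with named rows and columns.
#' @export
contingency_table <- function(rater_a, rater_b, levels = NULL) {
  if (length(rater_a) != length(rater_b)) stop("raters must grade the same cases")
  if (is.null(levels))
    levels <- sort(unique(c(as.character(rater_a), as.character(rater_b))))
  a <- factor(rater_a, levels = levels)
  b <- factor(rater_b, levels = levels)
  as.matrix(table(a, b))
}

#' Cohen's kappa with large-sample Z score
#'
#' Chance-corrected agreement between two raters on the same cases:
#' `kappa = (po - pe) / (1 - pe)` with observed agreement `po = trace / n`
#' and chance agreement `pe = sum_i row_i * col_i / n^2`.  Significance is
#' tested against the null of independent raters with the large-sample null
#' variance
#' `Var0 = [pe + pe^2 - sum_i p_i. * p_.i * (p_i. + p_.i)] / (n (1 - pe)^2)`,
#' giving `Z = kappa / sqrt(Var0)` and a two-sided normal p-value; agreement
#' is significant when |Z| > 1.96 at the 5% level.  The qualitative band is
#' excellent (kappa > 0.8), good (> 0.6), moderate (> 0.4), else poor.
#'
#' @param table square counts matrix (rows = rater A / system, columns =
#'   rater B / clinician), total count >= 2.
#' @return an object of class `kappa_result`: `kappa`, `z`, `p_value`,
#'   `band`, `po`, `pe`, `n`.
#' @export
#' @examples
#' tab <- matrix(c(8, 0, 0, 0, 9, 1, 0, 0, 6), 3, byrow = TRUE)
#' cohen_kappa(tab)
cohen_kappa <- function(table) {
  M <- as.matrix(table)
  if (nrow(M) != ncol(M)) stop("contingency table must be square")
  if (any(M < 0)) stop("negative counts")
  n <- sum(M)
  if (n < 2) stop("need at least 2 graded cases")
  po <- sum(diag(M)) / n
  p_row <- rowSums(M) / n
  p_col <- colSums(M) / n
  pe <- sum(p_row * p_col)
  if (1 - pe < .Machine$double.eps)
    stop("kappa undefined: both raters use a single category")
  kappa <- (po - pe) / (1 - pe)
  var0 <- (pe + pe^2 - sum(p_row * p_col * (p_row + p_col))) /
    (n * (1 - pe)^2)
  z <- kappa / sqrt(var0)
  structure(list(kappa = kappa, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 band = kappa_band(kappa),
                 po = po, pe = pe, n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("<kappa> %.3f (%s)  Z = %.3f  p = %.4g  n = %d\n",
              x$kappa, x$band, x$z, x$p_value, x$n))
  invisible(x)
}

#' Intraclass correlation for test-retest reliability
#'
#' Single-measurement ICC from the two-way mean-squares decomposition of a
#' balanced subjects x repeated-measurements matrix.  The default,
#' two-way mixed effects with absolute agreement -- ICC(A,1) in the
#' McGraw-Wong taxonomy, SPSS "two-way mixed, absolute agreement, single
#' measures" -- suits a fixed measurement device applied repeatedly to each
#' subject:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`.
#' The consistency variant ICC(C,1) `(MSR - MSE)/(MSR + (k-1) MSE)` and the
#' one-way random ICC(1) are also available.  The 95% confidence interval
#' uses the F-distribution bounds of McGraw & Wong.  Bands: excellent
#' (> 0.9), good (> 0.75), moderate (> 0.5), else poor.
#'
#' @param data numeric matrix, subjects in rows (>= 2), repeated
#'   measurements in columns (>= 2), balanced (no missing cells).
#' @param model `"A-1"` (absolute agreement, default), `"C-1"`
#'   (consistency) or `"1"` (one-way random).
#' @param ci_level confidence level (default 0.95).
#' @return an object of class `icc_result`: `icc`, `ci95`, `band`, `model`,
#'   mean squares.
#' @export
icc <- function(data, model = c("A-1", "C-1", "1"), ci_level = 0.95) {
  model <- match.arg(model)
  X <- as.matrix(data)
  n <- nrow(X); k <- ncol(X)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 measurements")
  if (anyNA(X)) stop("balanced design required: no missing cells")
  grand <- mean(X)
  row_m <- rowMeans(X); col_m <- colMeans(X)
  SSR <- k * sum((row_m - grand)^2)        # between subjects
  SSC <- n * sum((col_m - grand)^2)        # between measurements
  SST <- sum((X - grand)^2)
  SSE <- SST - SSR - SSC                   # residual
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  MSW <- (SSC + SSE) / (n * (k - 1))       # within subjects (one-way)
  if (MSR <= 0 && MSE <= 0) stop("ICC undefined for constant data")

  alpha <- 1 - ci_level
  if (model == "1") {
    r <- (MSR - MSW) / (MSR + (k - 1) * MSW)
    Fobs <- MSR / MSW
    FL <- Fobs / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
    FU <- Fobs * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
    lo <- (FL - 1) / (FL + k - 1)
    hi <- (FU - 1) / (FU + k - 1)
  } else if (model == "C-1") {
    r <- (MSR - MSE) / (MSR + (k - 1) * MSE)
    Fobs <- MSR / MSE
    df2 <- (n - 1) * (k - 1)
    FL <- Fobs / stats::qf(1 - alpha / 2, n - 1, df2)
    FU <- Fobs * stats::qf(1 - alpha / 2, df2, n - 1)
    lo <- (FL - 1) / (FL + k - 1)
    hi <- (FU - 1) / (FU + k - 1)
  } else {
    r <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
    # McGraw & Wong (1996) CI for ICC(A,1) via Satterthwaite df
    a <- (k * r) / (n * (1 - r))
    b <- 1 + (k * r * (n - 1)) / (n * (1 - r))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    Fl <- stats::qf(1 - alpha / 2, n - 1, v)
    Fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (MSR - Fl * MSE) /
      (Fl * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    hi <- n * (Fu * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * Fu * MSR)
  }
  structure(list(icc = r, ci95 = c(lower = lo, upper = hi),
                 band = icc_band(r), model = model,
                 ms = c(MSR = MSR, MSC = MSC, MSE = MSE, MSW = MSW),
                 n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc> %s = %.3f (%s)  95%% CI [%.3f, %.3f]  %d subjects x %d measurements\n",
              x$model, x$icc, x$band, x$ci95[1], x$ci95[2], x$n, x$k))
  invisible(x)
}
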