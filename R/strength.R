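ACTIONS <- c("Grasp the cylinder", "Pinch objects with fingertip",
             "Grasp the ball", "Click objects with finger")

M_GRADES <- paste0("M", 0:5)

#' One-dimensional K-means by Lloyd iteration
#'
#' Partitions a set of muscle-strength maxima into `k` clusters by the
#' classical two-step iteration: assign each value to its nearest centre by
#' squared distance, then move each centre to the mean of its cluster, until
#' the assignment is stable (or 300 iterations).  Initial centres are drawn
#' by k-means++ seeding; the best of `n_restarts` runs by within-cluster sum
#' of squares (WCSS) is kept.  Centres are returned sorted ascending, so for
#' `k = 6` cluster 1 is the weakest interval (Lovett M0) and cluster 6 the
#' strongest (M5).
#'
#' @param values numeric vector, `length(values) >= k`, all finite.
#' @param k number of clusters (default 6, the Lovett scale).
#' @param seed integer seed for the restarts.
#' @param n_restarts number of seeded restarts (default 10).
#' @return an object of class `cluster_model`: `k`, sorted `centers`,
#'   `boundaries` (midpoints between adjacent centres), `assignments`
#'   (indices into the sorted centres), `n_per_cluster`, `wcss`.
#' @export
kmeans_fit <- function(values, k = 6, seed = 1L, n_restarts = 10) {
  values <- as.numeric(values)
  n <- length(values)
  if (any(!is.finite(values))) stop("values must be finite")
  if (n < k) stop(sprintf("need at least k = %d values, got %d", k, n))
  if (k > 1 && length(unique(values)) == 1L)
    stop("degenerate input: all values identical with k > 1")

  run_lloyd <- function(centers) {
    assign_old <- rep(0L, n)
    for (iter in seq_len(300L)) {
      d2 <- outer(values, centers, function(x, m) (x - m)^2)
      assign_new <- max.col(-d2, ties.method = "first")
      # re-seed any emptied cluster at the point farthest from its centre
      for (j in seq_len(k)) {
        if (!any(assign_new == j)) {
          far <- which.max(d2[cbind(seq_len(n), assign_new)])
          centers[j] <- values[far]
          assign_new[far] <- j
        }
      }
      if (identical(assign_new, assign_old)) break
      assign_old <- assign_new
      centers <- vapply(seq_len(k), function(j) mean(values[assign_new == j]),
                        numeric(1))
    }
    wcss <- sum((values - centers[assign_new])^2)
    list(centers = centers, assignments = assign_new, wcss = wcss)
  }

  # k-means++ seeding: first centre uniform, later centres with probability
  # proportional to squared distance from the nearest chosen centre
  seed_pp <- function() {
    centers <- numeric(k)
    centers[1] <- values[sample.int(n, 1L)]
    if (k > 1) for (j in 2:k) {
      d2 <- vapply(values, function(v) min((v - centers[seq_len(j - 1L)])^2),
                   numeric(1))
      if (all(d2 == 0)) centers[j] <- values[sample.int(n, 1L)]
      else centers[j] <- values[sample.int(n, 1L, prob = d2)]
    }
    centers
  }

  best <- NULL
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    fit <- run_lloyd(seed_pp())
    if (is.null(best) || fit$wcss < best$wcss - 1e-12) best <- fit
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  ord <- order(best$centers)
  centers <- best$centers[ord]
  relabel <- match(seq_along(ord), ord)
  assignments <- relabel[best$assignments]
  structure(list(k = as.integer(k), centers = centers,
                 boundaries = (centers[-1] + centers[-k]) / 2,
                 assignments = assignments,
                 n_per_cluster = tabulate(assignments, nbins = k),
                 wcss = best$wcss),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k=%d  WCSS=%.4g\n", x$k, x$wcss))
  cat("  centers:   ", paste(signif(x$centers, 5), collapse = " "), "\n")
  cat("  boundaries:", paste(signif(x$boundaries, 5), collapse = " "), "\n")
  invisible(x)
}

#' Interval cut points of a fitted cluster model
#'
#' The `k - 1` boundaries are the midpoints between adjacent sorted centres:
#' the one-dimensional Voronoi boundaries implied by the nearest-centre
#' assignment rule, so every training value falls in the interval of its own
#' cluster.
#'
#' @param model a fitted `cluster_model`.
#' @return numeric vector of `k - 1` strictly increasing cut points.
#' @export
interval_boundaries <- function(model) {
  if (!inherits(model, "cluster_model")) stop("not a fitted cluster_model")
  model$boundaries
}

#' Lovett muscle-strength grade of a force maximum
#'
#' Locates `overall_max` among the model's interval boundaries: the lowest
#' interval is M0 (worst), the highest M5 (normal).  A value exactly on a
#' boundary falls in the upper interval.
#'
#' @param overall_max maximum filtered force across actions.
#' @param model a fitted `cluster_model` with `k = 6`.
#' @return a factor with levels `M0`..`M5`.
#' @export
grade_strength <- function(overall_max, model) {
  if (!inherits(model, "cluster_model")) stop("not a fitted cluster_model")
  if (model$k != 6L) stop("Lovett grading requires k = 6 clusters")
  idx <- findInterval(overall_max, model$boundaries, left.open = FALSE)
  factor(M_GRADES[idx + 1L], levels = M_GRADES)
}

#' Assess hand muscle strength from action recordings
#'
#' Each pressure recording (one per action) is smoothed per channel with the
#' EWA filter; the per-action maximum force and the overall maximum across
#' actions are extracted, and the overall maximum is graded against the
#' population cluster model.
#'
#' @param recordings list of pressure `recording`s; `meta$action` names the
#'   action.
#' @param model a fitted `cluster_model` with `k = 6`.
#' @param config a [run_config()].
#' @return an object of class `strength_result`: `per_action_max`,
#'   `overall_max`, `grade`.
#' @export
assess_strength <- function(recordings, model, config = run_config()) {
  if (length(recordings) < 1L) stop("need at least one action recording")
  per_action <- numeric(length(recordings))
  actions <- character(length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    stopifnot(inherits(rec, "recording"))
    if (rec$kind != "pressure") stop("assess_strength expects pressure recordings")
    actions[i] <- rec$meta$action %||% "unknown"
    filt <- apply(rec$data, 2L, ewa_filter, alpha = config$ewa_alpha)
    per_action[i] <- max(filt)
  }
  overall <- max(per_action)
  structure(list(per_action_max = stats::setNames(per_action, actions),
                 overall_max = overall,
                 grade = grade_strength(overall, model)),
            class = "strength_result")
}

#' @export
print.strength_result <- function(x, ...) {
  cat(sprintf("<strength> grade %s  overall max force=%.3f\n",
              as.character(x$grade), x$overall_max))
  invisible(x)
}
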