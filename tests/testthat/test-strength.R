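test_that("k-means handles the degenerate and single-cluster cases", {
  vals <- c(3, 7, 1, 9, 4)
  m <- kmeans_fit(vals, k = 1)
  expect_equal(m$centers, mean(vals))  # one cluster: centre is the mean
  expect_equal(m$n_per_cluster, 5L)
  expect_error(kmeans_fit(c(1, 2), k = 3), "at least k")
  expect_error(kmeans_fit(rep(5, 10), k = 2), "degenerate")
})

test_that("k-means attains the exhaustive global optimum on tiny inputs", {
  set.seed(13)
  for (rep in 1:3) {
    vals <- round(runif(7, 0, 20), 2)
    fit <- kmeans_fit(vals, k = 2, seed = rep)
    expect_equal(fit$wcss, bruteforce_kmeans_wcss(vals, 2), tolerance = 1e-9)
  }
})

test_that("k-means recovers six well-separated blob centres", {
  set.seed(1)
  truth <- seq(0, 50, by = 10)
  vals <- rnorm(60, mean = rep(truth, each = 10), sd = 0.5)
  fit <- kmeans_fit(vals, k = 6, seed = 17)
  expect_true(all(abs(fit$centers - truth) < 0.5))
  # with well-separated blobs the optimum is the per-blob empirical means
  expect_equal(fit$centers,
               as.numeric(tapply(vals, rep(1:6, each = 10), mean)),
               tolerance = 1e-9)
  expect_true(all(diff(fit$centers) > 0))       # sorted ascending
  expect_equal(sum(fit$n_per_cluster), 60L)
  # determinism for fixed seed and data
  fit2 <- kmeans_fit(vals, k = 6, seed = 17)
  expect_identical(fit$centers, fit2$centers)
  expect_identical(fit$assignments, fit2$assignments)
  # independent cross-check: stats::kmeans started at our centres cannot
  # improve the within-cluster sum of squares
  ref <- stats::kmeans(vals, centers = matrix(fit$centers), iter.max = 100)
  expect_equal(fit$wcss, ref$tot.withinss, tolerance = 1e-8)
})

test_that("interval boundaries are centre midpoints consistent with assignment", {
  set.seed(19)
  vals <- c(rnorm(20, 5), rnorm(20, 20), rnorm(20, 40))
  fit <- kmeans_fit(vals, k = 3, seed = 19)
  expect_equal(interval_boundaries(fit),
               (fit$centers[-1] + fit$centers[-3]) / 2)
  # every training value falls inside the interval of its own cluster
  bins <- findInterval(vals, interval_boundaries(fit)) + 1L
  expect_equal(bins, fit$assignments)
  expect_error(interval_boundaries(list()), "cluster_model")
})

test_that("strength grading is half-open, monotone and spans M0..M5", {
  centers <- seq(5, 55, by = 10)
  model <- structure(list(k = 6L, centers = centers,
                          boundaries = (centers[-1] + centers[-6]) / 2),
                     class = "cluster_model")
  expect_equal(as.character(grade_strength(0, model)), "M0")
  expect_equal(as.character(grade_strength(100, model)), "M5")
  # exactly on a boundary -> upper interval
  expect_equal(as.character(grade_strength(10, model)), "M1")
  g <- as.integer(grade_strength(seq(0, 60, by = 0.5), model))
  expect_true(all(diff(g) >= 0))
  bad <- structure(list(k = 5L), class = "cluster_model")
  expect_error(grade_strength(1, bad), "k = 6")
})

test_that("assess_strength grades simulated action sets as intended", {
  pop <- simulate_strength_population(seed = 23)
  model <- kmeans_fit(pop, k = 6, seed = 23)

  actions <- names(pdglove:::ACTION_TEMPLATES)
  healthy <- lapply(seq_along(actions), function(i)
    simulate_action_pressure(actions[i], strength_level = 5, seed = 23 + i))
  res <- assess_strength(healthy, model)
  expect_true(as.character(res$grade) %in% c("M4", "M5"))
  expect_equal(unname(which.max(res$per_action_max)),
               which(actions == "Grasp the cylinder"))

  zero <- list(recording(matrix(0, 100, 7), kind = "pressure",
                         meta = list(action = actions[1])))
  expect_equal(as.character(assess_strength(zero, model)$grade), "M0")

  # monotonicity: increasing every pressure never decreases the grade
  grades <- sapply(0:5, function(lv) {
    recs <- lapply(seq_along(actions), function(i)
      simulate_action_pressure(actions[i], strength_level = lv, seed = 23 + i))
    as.integer(assess_strength(recs, model)$grade)
  })
  expect_true(all(diff(grades) >= 0))
})
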