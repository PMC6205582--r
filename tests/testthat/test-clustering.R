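test_that("seed selection is extremal with lowest-index tie-breaking", {
  m <- vec1(c(0, 1, 9, 10))            # mean 5: distances 5,4,4,5 -> tie {1,4}
  expect_equal(select_seed(m, "max_dist_from_mean"), 1)
  expect_equal(select_seed(vec1(42)), 1)
  # a vector equal to the time axis maximizes |r|
  m2 <- rbind(jitterless = 1:6 + c(0.3, -0.2, 0.1, 0, -0.4, 0.2),
              linear = 1:6,
              flat = rep(2, 6))
  expect_equal(select_seed(m2, "max_abs_time_correlation", times = 1:6), 2)
  # constant vectors get correlation 0, never win
  expect_equal(select_seed(rbind(rep(1, 4), c(1, 2, 3, 4)),
                           "max_abs_time_correlation", times = 1:4), 2)
})

test_that("farthest-point generation follows the worked examples", {
  m <- vec1(c(0, 1, 9, 10))
  cen <- farthest_point_centers(m, seed = 1, k = 2)
  expect_equal(attr(cen, "indices"), c(1, 4))       # 0 then 10
  expect_equal(unname(cen[, 1]), c(0, 10))
  # k = n: every vector a center, D_max = 0
  cen_n <- farthest_point_centers(m, seed = 1, k = 4)
  expect_equal(sort(attr(cen_n, "indices")), 1:4)
  # D_stop = 2: after {0, 10} the distances are {0,1,1,0}, so stop
  cen_s <- farthest_point_centers(m, seed = 1, D_stop = 2)
  expect_equal(attr(cen_s, "indices"), c(1, 4))
  expect_error(farthest_point_centers(m, seed = 1, k = 9), "exceeds")
  expect_error(farthest_point_centers(m, seed = 1), "give k")
})

test_that("farthest-point centers match the brute-force oracle on random instances", {
  set.seed(2024)
  for (rep in 1:25) {
    n <- sample(5:60, 1)
    d <- sample(1:8, 1)
    k <- sample(2:min(8, n), 1)
    m <- matrix(rnorm(n * d), n, d)
    seed <- select_seed(m)
    expect_identical(attr(farthest_point_centers(m, seed, k = k), "indices"),
                     bf_farthest_centers(m, seed, k))
  }
})

test_that("Lloyd refinement converges to the worked fixed point", {
  m <- vec1(c(0, 1, 9, 10))
  fit <- lloyd_refine(m, vec1(c(0, 10)), update = "mean")
  expect_equal(unname(fit$centers[, 1]), c(0.5, 9.5))
  expect_equal(unname(fit$cluster), c(1, 1, 2, 2))
  # centers already at the cluster means: nothing moves
  fit0 <- lloyd_refine(m, vec1(c(0.5, 9.5)), update = "mean")
  expect_equal(unname(fit0$centers[, 1]), c(0.5, 9.5))
  expect_equal(fit0$iterations, 1)  # one no-op update pass
  # median update with one center
  fitm <- lloyd_refine(vec1(c(0, 1, 100)), vec1(50), update = "median")
  expect_equal(unname(fitm$centers[1, 1]), 1)
})

test_that("WCSS is non-increasing over Lloyd iterations from random starts", {
  set.seed(7)
  m <- matrix(rnorm(80 * 5), 80, 5)
  for (r in 1:20) {
    init <- m[sample(80, 4), ]
    fit <- lloyd_refine(m, init, update = "mean")
    expect_true(all(diff(fit$wcss_trace) <= 1e-9))
  }
})

test_that("the full deterministic pipeline is reproducible run to run", {
  sim <- simulate_timecourse(simulation_spec(n_peaks = 60, seed = 10))
  pr <- time_profiles(control_correct(sim$dataset, "control", window = 5,
                                      stat = "median"),
                      window = 5, stat = "median")
  vs <- build_input_vectors(pr)
  f1 <- dkmeanspp(vs, k = 6)
  f2 <- dkmeanspp(vs, k = 6)
  expect_identical(f1$cluster, f2$cluster)
  expect_identical(f1$centers, f2$centers)
  expect_identical(f1$metrics, f2$metrics)
})

test_that("seeded random k-means baseline is reproducible and finds planted optima", {
  m <- vec1(c(0, 1, 9, 10))
  b1 <- kmeans_baseline(m, k = 2, runs = 10, rng_seed = 3)
  b2 <- kmeans_baseline(m, k = 2, runs = 10, rng_seed = 3)
  expect_identical(b1$centers, b2$centers)
  expect_equal(sort(unname(b1$centers[, 1])), c(0.5, 9.5))  # global optimum
  k1 <- kmeans_baseline(m, k = 1, runs = 3, rng_seed = 1)
  expect_equal(unname(k1$centers[1, 1]), 5)          # grand mean
  expect_error(kmeans_baseline(m, k = 9), "exceeds")
})

test_that("dispersion averages the closest fraction of vectors", {
  m <- vec1(c(0, 1, 2, 3))
  fit <- lloyd_refine(m, vec1(0), update = "mean", max_iter = 0)
  # force known D_i by centering at 0: distances are 0,1,2,3
  fit$D_i <- c(0, 1, 2, 3)
  expect_equal(dispersion(fit, 0.5), 0.5)
  expect_equal(dispersion(fit, 1), 1.5)
  # k = n: all distances zero for any fraction
  fitn <- dkmeanspp(m, k = 4)
  expect_equal(dispersion(fitn, 0.3), 0)
  expect_equal(dispersion(fitn, 1), 0)
  expect_lte(fitn$metrics[["D_closest10"]], fitn$metrics[["D"]])
})

test_that("silhouette matches brute-force enumeration and its conventions", {
  m <- vec1(c(0, 1, 10, 11))
  fit <- dkmeanspp(m, k = 2)
  s <- silhouette_width(fit)
  expect_equal(unname(s$widths[1]), (10.5 - 1) / 10.5, tolerance = 1e-4)
  expect_equal(s$mean, mean(bf_silhouette(m, unname(fit$cluster))),
               tolerance = 1e-9)
  expect_equal(s$mean, 0.8997, tolerance = 1e-3)
  # all-singleton clustering: mean silhouette 0 by convention
  fit4 <- dkmeanspp(m, k = 4)
  expect_equal(silhouette_width(fit4)$mean, 0)
  # bounds on a random instance
  set.seed(3)
  m2 <- matrix(rnorm(40 * 3), 40, 3)
  fit2 <- dkmeanspp(m2, k = 5)
  s2 <- silhouette_width(fit2)
  expect_true(all(s2$widths <= 1 & s2$widths >= -1))
  expect_equal(unname(s2$widths), bf_silhouette(m2, unname(fit2$cluster)),
               tolerance = 1e-9)
  expect_error(silhouette_width(dkmeanspp(m, k = 1)), "k >= 2")
})

test_that("spherical-Gaussian BIC matches the closed form", {
  fit1 <- dkmeanspp(vec1(c(-1, 1)), k = 1)
  expect_equal(as.numeric(bic_score(fit1)), -3.5310, tolerance = 1e-4)
  fit2 <- dkmeanspp(vec1(c(-2, 2)), k = 1)
  expect_equal(as.numeric(bic_score(fit2)), -4.9173, tolerance = 1e-4)
  # k = n on distinct points: zero residuals trigger the variance floor
  fit3 <- dkmeanspp(vec1(c(-1, 0, 1)), k = 3)
  expect_true(attr(bic_score(fit3), "degenerate"))
})

test_that("well-separated templates are recovered exactly with high silhouette", {
  sim <- simulate_timecourse(simulation_spec(n_peaks = 100, seed = 21,
                                             noise_sd = 0.3, amplitude = 12,
                                             batch_offsets = c(0, 0)))
  ds <- control_correct(sim$dataset, "control", window = 5, stat = "median")
  vs <- build_input_vectors(time_profiles(ds, window = 5, stat = "median"))
  fit <- dkmeanspp(vs, k = 5)
  truth <- sim$truth$template_id[rownames(vs)]
  # exact recovery up to label permutation
  tab <- table(fit$cluster, truth)
  expect_equal(sum(apply(tab, 1, max)), nrow(vs))
  expect_gt(fit$metrics[["silhouette"]], 0.8)
})

test_that("model methods expose centers, fitted values, residuals and predictions", {
  m <- matrix(rnorm(30 * 4), 30, 4)
  fit <- dkmeanspp(m, k = 3)
  expect_identical(coef(fit), fit$centers)
  expect_equal(fitted(fit) + residuals(fit), unclass(fit$x),
               ignore_attr = TRUE)
  expect_identical(unname(predict(fit)), unname(fit$cluster))
  expect_equal(unname(predict(fit, fit$centers)), 1:3)
  expect_output(print(fit), "d-k-means\\+\\+")
  expect_output(print(summary(fit)), "per cluster")
})

test_that("outlier pre-filtering drops only extreme vectors", {
  set.seed(5)
  m <- rbind(matrix(rnorm(50 * 3), 50, 3), c(50, 50, 50))
  out <- drop_outlier_vectors(m, z = 3)
  expect_equal(nrow(out), 50)
  expect_equal(attr(out, "dropped"), "v51")
})
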