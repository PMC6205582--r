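# One batch, QCs at acq_order 1/3/5, samples in between; single peak.
qc_line_ds <- function(qc_y = c(1, 3, 5), smp_y = c(10, 20),
                       smp_ord = c(2, 4)) {
  make_tiny_ds(vec1(c(qc_y, smp_y)),
               group = c("QC", "QC", "QC", "g", "g"),
               time = c(NA, NA, NA, 1, 2),
               batch = "b1",
               acq_order = c(1, 3, 5, smp_ord))
}

test_that("qc_mean factors are the batch QC mean, constant over the batch", {
  ds <- make_tiny_ds(vec1(c(8, 10, 12, 50, 60)),
                     group = c("QC", "QC", "QC", "g", "g"),
                     time = c(NA, NA, NA, 1, 2), batch = "b1",
                     acq_order = 1:5)
  cf <- correction_factors(ds, method = "qc_mean")
  expect_equal(unname(cf$C[, 1]), rep(10, 5))
  # default rescale: per-peak median of all QC intensities
  expect_equal(unname(cf$R[, 1]), rep(10, 5))
})

test_that("qc_linear evaluates the QC least-squares line at each acq_order", {
  ds <- qc_line_ds()
  # independent oracle: normal equations on the 3 QC points
  xo <- c(1, 3, 5); yo <- c(1, 3, 5)
  beta <- solve(t(cbind(1, xo)) %*% cbind(1, xo), t(cbind(1, xo)) %*% yo)
  expect_equal(unname(beta), matrix(c(0, 1), 2, 1), tolerance = 1e-12)
  cf <- correction_factors(ds, method = "qc_linear")
  expect_equal(unname(cf$C[ds$obs$acq_order == 4, 1]), 4, tolerance = 1e-12)
  expect_equal(unname(cf$C[, 1]), ds$obs$acq_order, tolerance = 1e-12)
  # trend-modelled correction with R = median of original QC intensities
  corrected <- apply_correction(ds, cf)
  expect_equal(unname(corrected$X[4, 1]), 10 - 2 + 3)
})

test_that("insufficient QCs and zero multiplicative factors are errors", {
  ds <- make_tiny_ds(vec1(c(5, 7)), group = c("QC", "g"), time = c(NA, 1),
                     batch = "b1", acq_order = 1:2)
  expect_error(correction_factors(ds, method = "qc_linear"), "b1")
  ds0 <- make_tiny_ds(vec1(c(0, 7)), group = c("QC", "g"), time = c(NA, 1),
                      batch = "b1", acq_order = 1:2)
  expect_error(correction_factors(ds0, method = "qc_mean",
                                  form = "multiplicative"), "zero")
})

test_that("both correction forms follow their equations and identity case", {
  ds <- make_tiny_ds(vec1(10), group = "g", time = 1, batch = "b1")
  cf <- structure(list(C = vec1(12), R = vec1(5), method = "qc_mean",
                       form = "additive", window = NULL,
                       rescale = "qc_median"), class = "mtb_correction")
  expect_equal(unname(apply_correction(ds, cf)$X[1, 1]), 3)      # 10 - 12 + 5
  cf$form <- "multiplicative"; cf$C <- vec1(5); cf$R <- vec1(2)
  expect_equal(unname(apply_correction(ds, cf)$X[1, 1]), 4)      # 10 * 2 / 5
  # C == R everywhere leaves the data untouched in both forms
  for (form in c("additive", "multiplicative")) {
    cfi <- cf; cfi$form <- form; cfi$C <- vec1(7); cfi$R <- vec1(7)
    expect_equal(apply_correction(ds, cfi)$X, ds$X)
  }
})

test_that("additive qc_mean correction preserves within-batch differences", {
  sim <- simulate_timecourse(simulation_spec(n_peaks = 8, seed = 11,
                                             batch_offsets = c(0, 9)))
  ds <- impute_missing(sim$dataset, quiet = TRUE)
  cor_ds <- apply_correction(ds, correction_factors(ds, method = "qc_mean"))
  for (b in unique(ds$obs$batch)) {
    rows <- which(ds$obs$batch == b)
    expect_equal(diff(ds$X[rows, 3]), diff(cor_ds$X[rows, 3]),
                 tolerance = 1e-9)
  }
})

test_that("missing intensities block correction until imputed", {
  X <- vec1(c(5, NA, 7, 8))
  ds <- make_tiny_ds(X, group = c("QC", "g", "g", "g"),
                     time = c(NA, 1, 1, 2), batch = "b1", acq_order = 1:4,
                     replicate = c("q", "r1", "r2", "r1"))
  expect_error(correction_factors(ds, method = "qc_mean"), "impute")
  imp <- impute_missing(ds, quiet = TRUE)
  expect_equal(unname(imp$X[2, 1]), 7)   # (group g, time 1) median
  expect_silent(correction_factors(imp, method = "qc_mean"))
})

test_that("scaling methods match their definitions", {
  ds <- make_tiny_ds(vec1(c(0, 2)), group = c("g", "g"), time = c(1, 2),
                     batch = "b1")
  expect_equal(unname(scale_peaks(ds, "pareto")$X[, 1]),
               c(-0.84090, 0.84090), tolerance = 1e-5)
  expect_equal(unname(scale_peaks(ds, "range")$X[, 1]), c(-0.5, 0.5))
  # auto scaling: mean 0, sd 1 for an arbitrary peak
  set.seed(42)
  ds2 <- make_tiny_ds(vec1(rnorm(20, 50, 7)), group = "g",
                      time = 1:20, batch = "b1")
  a <- scale_peaks(ds2, "auto")$X[, 1]
  expect_equal(mean(a), 0, tolerance = 1e-9)
  expect_equal(sd(a), 1, tolerance = 1e-9)
  # vast = auto * mean/sd
  v <- scale_peaks(ds2, "vast")$X[, 1]
  expect_equal(v, a * mean(ds2$X[, 1]) / sd(ds2$X[, 1]), tolerance = 1e-9)
})

test_that("zero-variance peaks are dropped with a warning, not an error", {
  ds <- make_tiny_ds(cbind(c(1, 1, 1), c(1, 2, 3)),
                     group = "g", time = 1:3, batch = "b1")
  expect_warning(out <- scale_peaks(ds, "auto"), "zero-spread")
  expect_identical(out$peaks$peak_id, "p2")
})

test_that("Bhattacharyya distance follows the Gaussian closed form", {
  expect_equal(bhattacharyya_gaussian(0, 1, 0, 1), 0)
  expect_equal(bhattacharyya_gaussian(0, 1, 2, 1), 0.5)
  # asymmetric variances, against the formula written out once more
  m1 <- 1; s1 <- 2; m2 <- 4; s2 <- 0.5
  expect_equal(bhattacharyya_gaussian(m1, s1, m2, s2),
               0.25 * log(0.25 * (s1 / s2 + s2 / s1 + 2)) +
                 0.25 * (m1 - m2)^2 / (s1 + s2))
})

test_that("quality report: identical replicates give RSD 0; identical batches give distance 0", {
  X <- vec1(c(5, 5, 5, 5, 7, 7))
  ds <- make_tiny_ds(X, group = c("g", "g", "g", "g", "h", "h"),
                     time = c(1, 1, 2, 2, 1, 1), batch = rep(c("b1", "b2"), 3),
                     replicate = c("r1", "r2", "r1", "r2", "r1", "r2"))
  q <- correction_quality(ds, ds)
  expect_equal(q$peaks$rsd_before, 0)
  # batches b1 and b2 see identical value sets -> zero distance
  expect_equal(q$peaks$bhattacharyya_before, 0)
})

test_that("injected constant offsets: qc_mean shrinks batch separation; drift: qc_linear wins", {
  sim <- simulate_timecourse(simulation_spec(n_peaks = 40, seed = 5,
                                             batch_offsets = c(0, 8)))
  ds <- impute_missing(sim$dataset, quiet = TRUE)
  after <- apply_correction(ds, correction_factors(ds, method = "qc_mean"))
  q <- correction_quality(ds, after)
  expect_lt(q$summary[["bhattacharyya_after"]],
            0.1 * q$summary[["bhattacharyya_before"]])

  simd <- simulate_timecourse(simulation_spec(n_peaks = 40, seed = 6,
                                              batch_offsets = c(0, 0),
                                              drift = c(0.25, 0)))
  dsd <- impute_missing(simd$dataset, quiet = TRUE)
  q_mean <- correction_quality(dsd, apply_correction(
    dsd, correction_factors(dsd, method = "qc_mean")))
  q_lin <- correction_quality(dsd, apply_correction(
    dsd, correction_factors(dsd, method = "qc_linear")))
  expect_lt(q_lin$summary[["bhattacharyya_after"]],
            q_mean$summary[["bhattacharyya_after"]])
})

test_that("background correction beats qc_linear on replicate RSD when QCs mislead", {
  # QC trend differs from the sample trend: QCs drift, samples do not
  sim <- simulate_timecourse(simulation_spec(n_peaks = 30, seed = 8,
                                             batch_offsets = c(0, 0)))
  ds <- impute_missing(sim$dataset, quiet = TRUE)
  qc <- ds$obs$group == "QC"
  # impose a strong artificial drift on the QC injections only
  ds$X[qc, ] <- ds$X[qc, ] + 0.6 * ds$obs$acq_order[qc]
  q_lin <- correction_quality(ds, apply_correction(
    ds, correction_factors(ds, method = "qc_linear")))
  q_bg <- correction_quality(ds, apply_correction(
    ds, correction_factors(ds, method = "background")))
  expect_lt(q_bg$summary[["rsd_after"]], q_lin$summary[["rsd_after"]])
})
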