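#' Correction factors for batch and drift removal
#'
#' Computes, per peak and observation, the correction factor C used to
#' remove between-batch offsets and within-batch acquisition-order drift,
#' together with the rescale value R that returns each peak to a working
#' intensity scale. The corrected intensity is then
#' `X - C + R` (additive form) or `X * R / C` (multiplicative form); see
#' [apply_correction()].
#'
#' Methods:
#' \describe{
#'   \item{`qc_mean`}{C is constant per (peak, batch): the mean of that
#'     batch's QC intensities.}
#'   \item{`qc_linear`}{C follows the least-squares line of QC intensity
#'     against acquisition order within each batch, evaluated at every
#'     observation's acquisition order. Needs >= 2 QCs per batch.}
#'   \item{`qc_moving_median`}{C is the moving median (window over
#'     acquisition order) of the batch's QC intensities; an observation
#'     with no QC inside its window takes the nearest QC's value.}
#'   \item{`background`}{C is the moving median over acquisition order of
#'     all non-QC observations in the batch — a smooth sample-driven
#'     trend for designs where the QCs do not track the experimental
#'     drift. Window defaults to 10\% of the batch's acquisition span.}
#' }
#'
#' @param ds an [mtb_dataset()] (no missing values; see
#'   [impute_missing()]).
#' @param method one of `"qc_mean"`, `"qc_linear"`, `"qc_moving_median"`,
#'   `"background"`.
#' @param window total moving-window width in acquisition-order units
#'   (centered, closed); used by the moving-median methods. `NULL` for
#'   `background` means 10\% of the batch span.
#' @param rescale `"qc_median"` (per-peak median of all QC intensities;
#'   default for QC methods), `"global_mean"` (per-peak mean over all
#'   non-QC observations; default for `background`) or `"batch_mean"`
#'   (mean of the batch's own non-QC intensities — this recenters each
#'   batch at its own level, deliberately preserving between-batch
#'   differences). The first two are constant per peak across batches,
#'   which is what lets subtracting C and re-adding R remove
#'   between-batch offsets.
#' @param form `"additive"` or `"multiplicative"`.
#' @return An object of class `mtb_correction` with matrices `C` and `R`
#'   (both observations x peaks), the method, form and window used.
#' @export
correction_factors <- function(ds,
                               method = c("qc_mean", "qc_linear",
                                          "qc_moving_median", "background"),
                               window = NULL,
                               rescale = NULL,
                               form = c("additive", "multiplicative")) {
  stopifnot(inherits(ds, "mtb_dataset"))
  method <- match.arg(method)
  form <- match.arg(form)
  if (is.null(rescale))
    rescale <- if (method == "background") "global_mean" else "qc_median"
  rescale <- match.arg(rescale, c("qc_median", "batch_mean", "global_mean"))
  if (anyNA(ds$X))
    stop("dataset contains missing intensities; impute first (impute_missing)")

  qc <- qc_mask(ds)
  batches <- unique(ds$obs$batch)
  X <- ds$X
  C <- matrix(NA_real_, nrow(X), ncol(X), dimnames = dimnames(X))
  R <- matrix(NA_real_, nrow(X), ncol(X), dimnames = dimnames(X))

  min_qc <- switch(method, qc_mean = 1L, qc_linear = 2L, qc_moving_median = 1L, 0L)
  for (b in batches) {
    in_b <- ds$obs$batch == b
    qc_b <- which(in_b & qc)
    smp_b <- which(in_b & !qc)
    if (length(qc_b) < min_qc)
      stop("batch '", b, "' has ", length(qc_b), " QC observation(s); method '",
           method, "' needs >= ", min_qc)
    if (method == "background" && length(smp_b) < 2)
      stop("batch '", b, "' has fewer than 2 non-QC observations; ",
           "background correction needs >= 2")
    ord_all <- ds$obs$acq_order[in_b]
    span <- diff(range(ord_all))
    w <- window
    if (is.null(w)) {
      if (method == "background") w <- 0.1 * span
      else if (method == "qc_moving_median")
        stop("window must be given for qc_moving_median")
    }

    C[in_b, ] <- switch(method,
      qc_mean = matrix(colMeans(X[qc_b, , drop = FALSE]),
                       nrow = sum(in_b), ncol = ncol(X), byrow = TRUE),
      qc_linear = {
        xo <- ds$obs$acq_order[qc_b]
        fit <- stats::lm.fit(cbind(1, xo), X[qc_b, , drop = FALSE])
        beta <- fit$coefficients          # 2 x n_peaks
        cbind(1, ds$obs$acq_order[in_b]) %*% beta
      },
      qc_moving_median = moving_stat_eval(ds$obs$acq_order[qc_b],
                                          X[qc_b, , drop = FALSE],
                                          ds$obs$acq_order[in_b], w),
      background = moving_stat_eval(ds$obs$acq_order[smp_b],
                                    X[smp_b, , drop = FALSE],
                                    ds$obs$acq_order[in_b], w))

    if (rescale == "batch_mean")
      R[in_b, ] <- matrix(colMeans(X[smp_b, , drop = FALSE]),
                          nrow = sum(in_b), ncol = ncol(X), byrow = TRUE)
  }
  if (rescale == "qc_median") {
    if (!any(qc)) stop("no QC observations; rescale 'qc_median' unavailable")
    R[] <- matrix(apply(X[qc, , drop = FALSE], 2, stats::median),
                  nrow = nrow(X), ncol = ncol(X), byrow = TRUE)
  } else if (rescale == "global_mean") {
    R[] <- matrix(colMeans(X[!qc, , drop = FALSE]),
                  nrow = nrow(X), ncol = ncol(X), byrow = TRUE)
  }

  if (form == "multiplicative" && any(C == 0))
    stop("zero correction factor incompatible with multiplicative form")
  structure(list(C = C, R = R, method = method, form = form,
                 window = window, rescale = rescale),
            class = "mtb_correction")
}

# Evaluate a centered moving median of (ord, Y) at positions `at`.
# Closed window of total width `w`; empty neighborhoods fall back to the
# nearest support point.
moving_stat_eval <- function(ord, Y, at, w) {
  out <- matrix(NA_real_, length(at), ncol(Y))
  half <- w / 2
  for (j in seq_along(at)) {
    sel <- abs(ord - at[j]) <= half
    if (!any(sel)) sel <- which.min(abs(ord - at[j]))
    sub <- Y[sel, , drop = FALSE]
    out[j, ] <- apply(sub, 2, stats::median)
  }
  out
}

#' @export
print.mtb_correction <- function(x, ...) {
  cat("mtb_correction: method=", x$method, ", form=", x$form,
      ", rescale=", x$rescale, "\n", sep = "")
  invisible(x)
}

#' Apply correction factors to a dataset
#'
#' Additive form: `X' = X - C + R`. Multiplicative form: `X' = X * R / C`.
#' The additive form preserves within-batch differences whenever C is
#' constant per (peak, batch); the multiplicative form preserves ratios.
#'
#' @param ds an [mtb_dataset()] with no missing intensities.
#' @param cf an `mtb_correction` from [correction_factors()].
#' @return The corrected `mtb_dataset` (metadata unchanged).
#' @export
apply_correction <- function(ds, cf) {
  stopifnot(inherits(ds, "mtb_dataset"), inherits(cf, "mtb_correction"))
  if (!all(dim(cf$C) == dim(ds$X)))
    stop("correction factor dimensions do not match the dataset")
  if (anyNA(ds$X))
    stop("dataset contains missing intensities; impute first (impute_missing)")
  Xc <- if (cf$form == "additive") ds$X - cf$C + cf$R
        else {
          if (any(cf$C == 0)) stop("division by zero correction factor")
          ds$X * cf$R / cf$C
        }
  out <- ds
  out$X <- Xc
  out
}

#' Impute missing intensities
#'
#' Fills each missing cell with the median intensity of its
#' (peak, group, time) stratum; if the whole stratum is missing, the
#' per-peak median is used. Each imputation is reported via a message.
#'
#' @param ds an [mtb_dataset()].
#' @param quiet suppress the per-cell log messages.
#' @return The completed `mtb_dataset`.
#' @export
impute_missing <- function(ds, quiet = FALSE) {
  stopifnot(inherits(ds, "mtb_dataset"))
  X <- ds$X
  if (!anyNA(X)) return(ds)
  key <- paste(ds$obs$group, ds$obs$time, sep = "\r")
  for (j in seq_len(ncol(X))) {
    miss <- which(is.na(X[, j]))
    for (i in miss) {
      same <- which(key == key[i])
      v <- stats::median(X[same, j], na.rm = TRUE)
      if (is.na(v)) v <- stats::median(X[, j], na.rm = TRUE)
      if (is.na(v)) stop("peak ", ds$peaks$peak_id[j], " entirely missing")
      X[i, j] <- v
      if (!quiet)
        message("imputed ", ds$obs$obs_id[i], " / ", ds$peaks$peak_id[j],
                " = ", signif(v, 6))
    }
  }
  out <- ds
  out$X <- X
  out
}

#' Scale peaks to comparable influence
#'
#' Per peak, the (optionally mean-centered) intensities are divided by a
#' spread measure so that high-abundance peaks do not dominate distance
#' based analyses: `auto` divides by the sample SD (unit variance),
#' `pareto` by the square root of the SD, `range` by max - min, and
#' `vast` additionally multiplies the auto-scaled value by mean/SD, down
#' weighting peaks with high relative variability.
#'
#' Peaks with zero spread carry no profile information and are removed
#' with a warning rather than producing non-finite values; the
#' significance filter would drop such flat peaks regardless.
#'
#' @param ds an [mtb_dataset()] with no missing intensities.
#' @param method `"auto"`, `"pareto"`, `"range"` or `"vast"`.
#' @param center subtract the per-peak mean first (default TRUE).
#' @return The scaled `mtb_dataset` (zero-spread peaks dropped).
#' @export
scale_peaks <- function(ds, method = c("auto", "pareto", "range", "vast"),
                        center = TRUE) {
  stopifnot(inherits(ds, "mtb_dataset"))
  method <- match.arg(method)
  if (anyNA(ds$X)) stop("dataset contains missing intensities; impute first")
  X <- ds$X
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  rng <- apply(X, 2, function(v) diff(range(v)))
  spread <- if (method == "range") rng else sdv
  flat <- spread == 0
  if (any(flat)) {
    warning(sum(flat), " zero-spread peak(s) removed before scaling: ",
            paste(utils::head(ds$peaks$peak_id[flat], 5), collapse = ", "),
            if (sum(flat) > 5) ", ..." else "")
    ds <- subset_dataset(ds, peaks = which(!flat))
    X <- ds$X; mu <- mu[!flat]; sdv <- sdv[!flat]; rng <- rng[!flat]
  }
  Xc <- if (center) sweep(X, 2, mu) else X
  Xs <- switch(method,
    auto = sweep(Xc, 2, sdv, "/"),
    pareto = sweep(Xc, 2, sqrt(sdv), "/"),
    range = sweep(Xc, 2, rng, "/"),
    vast = sweep(sweep(Xc, 2, sdv, "/"), 2, mu / sdv, "*"))
  out <- ds
  out$X <- Xs
  out
}

#' Quantify correction quality before and after
#'
#' Per peak: the replicate relative standard deviation (RSD, percent,
#' averaged over (group, time) cells with >= 2 replicates), the one-way
#' ANOVA F statistic contrasting between-group and within-group variance
#' over the experimental groups, and the mean pairwise univariate
#' Gaussian Bhattacharyya distance between batches. A good correction
#' lowers the RSD and the batch Bhattacharyya distance while preserving
#' (or raising) the group F statistic.
#'
#' @param before,after two [mtb_dataset()]s sharing metadata (pass the
#'   same dataset twice to profile a single state).
#' @return An object of class `mtb_quality`: list with `peaks` (one row
#'   per peak: `rsd_before`, `rsd_after`, `f_before`, `f_after`,
#'   `bhattacharyya_before`, `bhattacharyya_after`) and `summary`
#'   (across-peak medians).
#' @export
correction_quality <- function(before, after) {
  stopifnot(inherits(before, "mtb_dataset"), inherits(after, "mtb_dataset"))
  if (!identical(before$obs$obs_id, after$obs$obs_id))
    stop("before/after datasets do not share observations")
  one <- function(ds) {
    nqc <- !qc_mask(ds)
    X <- ds$X[nqc, , drop = FALSE]
    grp <- ds$obs$group[nqc]
    tim <- ds$obs$time[nqc]
    bat <- ds$obs$batch[nqc]
    cell <- paste(grp, tim, sep = "\r")
    rsd <- apply(X, 2, function(v) {
      per <- tapply(v, cell, function(w)
        if (length(w) >= 2 && mean(w) != 0) 100 * stats::sd(w) / abs(mean(w)) else NA_real_)
      if (all(is.na(per))) NA_real_ else mean(per, na.rm = TRUE)
    })
    fstat <- apply(X, 2, function(v) anova_f(v, grp))
    bh <- apply(X, 2, function(v) mean_pairwise_bhattacharyya(v, bat))
    data.frame(rsd = rsd, f = fstat, bhattacharyya = bh)
  }
  qb <- one(before)
  qa <- one(after)
  peaks <- data.frame(peak_id = before$peaks$peak_id,
                      rsd_before = qb$rsd, rsd_after = qa$rsd,
                      f_before = qb$f, f_after = qa$f,
                      bhattacharyya_before = qb$bhattacharyya,
                      bhattacharyya_after = qa$bhattacharyya)
  summary <- vapply(peaks[-1], stats::median, numeric(1), na.rm = TRUE)
  structure(list(peaks = peaks, summary = summary), class = "mtb_quality")
}

#' @export
print.mtb_quality <- function(x, ...) {
  cat("mtb_quality (across-peak medians):\n")
  print(round(x$summary, 4))
  invisible(x)
}

# One-way ANOVA F over groups with >= 2 members; NA when undefined.
anova_f <- function(v, grp) {
  keep <- grp %in% names(which(table(grp) >= 2))
  v <- v[keep]; grp <- factor(grp[keep])
  if (nlevels(grp) < 2) return(NA_real_)
  n <- length(v)
  gm <- tapply(v, grp, mean)
  ng <- tapply(v, grp, length)
  ssb <- sum(ng * (gm - mean(v))^2)
  ssw <- sum((v - gm[grp])^2)
  dfb <- nlevels(grp) - 1
  dfw <- n - nlevels(grp)
  if (ssw == 0 || dfw == 0) return(NA_real_)
  (ssb / dfb) / (ssw / dfw)
}

#' Univariate Gaussian Bhattacharyya distance
#'
#' Closed form for two normal distributions:
#' `DB = 1/4 log(1/4 (s1^2/s2^2 + s2^2/s1^2 + 2)) +
#'       1/4 (m1 - m2)^2 / (s1^2 + s2^2)`.
#'
#' @param m1,s1sq,m2,s2sq means and variances of the two distributions.
#' @return The distance (0 for identical distributions).
#' @export
bhattacharyya_gaussian <- function(m1, s1sq, m2, s2sq) {
  if (s1sq <= 0 || s2sq <= 0) return(NA_real_)
  0.25 * log(0.25 * (s1sq / s2sq + s2sq / s1sq + 2)) +
    0.25 * (m1 - m2)^2 / (s1sq + s2sq)
}

mean_pairwise_bhattacharyya <- function(v, bat) {
  bs <- names(which(table(bat) >= 2))
  if (length(bs) < 2) return(NA_real_)
  m <- tapply(v, bat, mean)[bs]
  s2 <- tapply(v, bat, stats::var)[bs]
  pairs <- utils::combn(length(bs), 2)
  d <- apply(pairs, 2, function(ij)
    bhattacharyya_gaussian(m[ij[1]], s2[ij[1]], m[ij[2]], s2[ij[2]]))
  mean(d, na.rm = TRUE)
}

#' Write a quality report to CSV plus a text summary
#'
#' @param q an `mtb_quality` from [correction_quality()].
#' @param path output CSV path; a `.txt` summary is written alongside.
#' @return Invisibly, the CSV path.
#' @export
write_quality_report <- function(q, path) {
  stopifnot(inherits(q, "mtb_quality"))
  utils::write.csv(q$peaks, path, row.names = FALSE)
  txt <- sub("\\.csv$", ".txt", path)
  writeLines(c("across-peak medians:",
               paste(names(q$summary), "=", signif(q$summary, 6))), txt)
  invisible(path)
}
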