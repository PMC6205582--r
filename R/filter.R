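#' Significance filter against the control group
#'
#' Flags peaks whose intensities never deviate from the control so that
#' scaling does not promote flat, noisy profiles into spurious clusters.
#' For each peak and each experimental group, all time points and
#' replicates of the group are pooled and compared with the pooled
#' control by a two-sided Welch t-test; the smallest of the per-group p
#' values (`p_min`) is kept and the peak is retained when
#' `p_min <= alpha`. The p values are used purely as a deviation score
#' for thresholding — no statistical conclusion is attached to them and
#' no multiplicity correction is applied.
#'
#' Degenerate pools are resolved deterministically: both pools constant
#' and equal gives p = 1 (flat vs flat), both constant but different
#' gives p = 0 (a deterministic shift).
#'
#' @param ds an [mtb_dataset()] containing the control and at least one
#'   experimental group, each with >= 2 values per peak.
#' @param control the control group's label.
#' @param alpha retention threshold in (0, 1).
#' @return An object of class `mtb_filter`: list with `table` (one row
#'   per peak: `peak_id`, per-group `p_<group>` columns, `p_min`,
#'   `included`) and `alpha`.
#' @export
significance_filter <- function(ds, control, alpha = 0.05) {
  stopifnot(inherits(ds, "mtb_dataset"), alpha > 0, alpha < 1)
  if (!control %in% ds$obs$group)
    stop("control group '", control, "' not present")
  groups <- setdiff(unique(ds$obs$group), c(control, "QC"))
  if (length(groups) == 0) stop("no experimental groups to test")
  ctl_rows <- which(ds$obs$group == control)
  if (length(ctl_rows) < 2) stop("control group needs >= 2 observations")

  pmat <- matrix(NA_real_, ncol(ds$X), length(groups),
                 dimnames = list(ds$peaks$peak_id, groups))
  for (g in groups) {
    rows <- which(ds$obs$group == g)
    if (length(rows) < 2) stop("group '", g, "' needs >= 2 observations")
    for (j in seq_len(ncol(ds$X)))
      pmat[j, g] <- welch_p(ds$X[rows, j], ds$X[ctl_rows, j])
  }
  p_min <- apply(pmat, 1, min)
  tab <- data.frame(peak_id = ds$peaks$peak_id,
                    pmat, p_min = p_min,
                    included = p_min <= alpha,
                    check.names = FALSE)
  names(tab)[seq_along(groups) + 1] <- paste0("p_", groups)
  rownames(tab) <- NULL
  structure(list(table = tab, alpha = alpha, control = control),
            class = "mtb_filter")
}

# Two-sided Welch p value with deterministic handling of constant pools.
welch_p <- function(x, y) {
  if (stats::var(x) == 0 && stats::var(y) == 0)
    return(if (mean(x) == mean(y)) 1 else 0)
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' @export
print.mtb_filter <- function(x, ...) {
  cat("mtb_filter: alpha = ", x$alpha, "; retained ",
      sum(x$table$included), " / ", nrow(x$table), " peaks\n", sep = "")
  invisible(x)
}

#' Optimize the retention threshold against manual trend labels
#'
#' Given peaks hand-labelled as showing a clear trend, no clear trend, or
#' undecided, searches the grid alpha = 0.001, 0.002, ..., 0.500 for the
#' threshold that best reproduces the labels: a match is a `clear_trend`
#' peak with `p_min <= alpha` or a `no_clear_trend` peak with
#' `p_min > alpha`; `undecided` peaks are ignored. Ties go to the
#' smallest alpha.
#'
#' @param p_min numeric vector of per-peak minimum p values (see
#'   [significance_filter()]).
#' @param labels character vector (same length) in `clear_trend`,
#'   `no_clear_trend`, `undecided`.
#' @return List with `alpha` (the optimum), `match_rate` (fraction of
#'   non-undecided labels reproduced) and `grid` (data frame of the full
#'   search path).
#' @export
optimize_alpha <- function(p_min, labels) {
  stopifnot(length(p_min) == length(labels))
  ok <- c("clear_trend", "no_clear_trend", "undecided")
  if (!all(labels %in% ok))
    stop("labels must be in: ", paste(ok, collapse = ", "))
  use <- labels != "undecided"
  if (!any(use)) stop("all labels are undecided; nothing to optimize against")
  p <- p_min[use]
  lab <- labels[use]
  grid <- seq(0.001, 0.5, by = 0.001)
  rate <- vapply(grid, function(a)
    mean((lab == "clear_trend" & p <= a) | (lab == "no_clear_trend" & p > a)),
    numeric(1))
  best <- which.max(rate)   # which.max returns the first (smallest alpha) tie
  list(alpha = grid[best], match_rate = rate[best],
       grid = data.frame(alpha = grid, match_rate = rate))
}

#' Apply a filter result to a dataset or input-vector set
#'
#' @param x an [mtb_dataset()] or `mtb_vectors` matrix.
#' @param filter an `mtb_filter` from [significance_filter()].
#' @return `x` restricted to the retained peaks.
#' @export
apply_filter <- function(x, filter) {
  stopifnot(inherits(filter, "mtb_filter"))
  keep <- filter$table$peak_id[filter$table$included]
  if (inherits(x, "mtb_dataset")) return(subset_dataset(x, peaks = keep))
  if (inherits(x, "mtb_vectors")) {
    # vector labels are peak_id or peak_id::group
    pid <- sub("::.*$", "", rownames(x))
    out <- x[pid %in% keep, , drop = FALSE]
    attributes(out)$layout <- attr(x, "layout")
    attr(out, "mode") <- attr(x, "mode")
    class(out) <- class(x)
    return(out)
  }
  stop("x must be an mtb_dataset or mtb_vectors")
}

#' Write a filter result as CSV
#'
#' @param filter an `mtb_filter`.
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
write_filter <- function(filter, path) {
  utils::write.csv(filter$table, path, row.names = FALSE)
  invisible(path)
}
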