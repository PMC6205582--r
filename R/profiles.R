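#' Moving mean/median smoothing of a time series
#'
#' Each point is replaced by the mean or median of all points within a
#' centered, closed window of total width `window` (the window is
#' truncated at the ends of the series rather than padded). `window = 0`
#' leaves the series unchanged; a window spanning the whole series
#' returns the global statistic at every point.
#'
#' @param time numeric vector of strictly increasing time coordinates.
#' @param value numeric vector of the same length.
#' @param window total window width in time units (>= 0).
#' @param stat `"mean"` or `"median"`. An even-sized median neighborhood
#'   averages the two central values.
#' @return Numeric vector of smoothed values at the input times.
#' @export
smooth_series <- function(time, value, window = 0, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  stopifnot(length(time) == length(value), length(time) > 0, window >= 0)
  if (is.unsorted(time, strictly = TRUE))
    stop("time coordinates must be strictly increasing")
  half <- window / 2
  f <- if (stat == "mean") mean else stats::median
  vapply(seq_along(time), function(i)
    f(value[abs(time - time[i]) <= half]), numeric(1))
}

#' Per-peak smoothed time trend of one experimental group
#'
#' Collapses the replicates at each time point with `stat`, then smooths
#' the collapsed series with [smooth_series()]. The result is the
#' single time-course profile of each peak in that group.
#'
#' @param ds an [mtb_dataset()].
#' @param group the group label (must exist; `"QC"` not allowed).
#' @param window smoothing window in time units (see [smooth_series()]).
#' @param stat `"mean"` or `"median"` — used both to collapse replicates
#'   and as the moving statistic.
#' @return An object of class `mtb_profiles`: a long data frame with
#'   columns `peak_id`, `group`, `time`, `value`.
#' @export
group_trend <- function(ds, group, window = 0, stat = c("mean", "median")) {
  stopifnot(inherits(ds, "mtb_dataset"))
  stat <- match.arg(stat)
  sel <- which(ds$obs$group == group)
  if (length(sel) == 0) stop("group '", group, "' not present in the dataset")
  times <- sort(unique(ds$obs$time[sel]))
  f <- if (stat == "mean") mean else stats::median
  collapse <- vapply(times, function(tt) {
    rows <- sel[ds$obs$time[sel] == tt]
    apply(ds$X[rows, , drop = FALSE], 2, f)
  }, numeric(ncol(ds$X)))                       # peaks x times
  if (ncol(ds$X) == 1) collapse <- matrix(collapse, nrow = 1)
  sm <- t(apply(collapse, 1, function(v) smooth_series(times, v, window, stat)))
  if (length(times) == 1) sm <- matrix(sm, ncol = 1)
  out <- data.frame(
    peak_id = rep(ds$peaks$peak_id, times = length(times)),
    group = group,
    time = rep(times, each = ncol(ds$X)),
    value = as.vector(sm))
  class(out) <- c("mtb_profiles", "data.frame")
  out
}

#' Smoothed trends for every (non-QC) group
#'
#' @param ds an [mtb_dataset()].
#' @param window,stat passed to [group_trend()].
#' @param groups groups to include (default: all non-QC groups in
#'   observation order).
#' @return An `mtb_profiles` long data frame covering all groups.
#' @export
time_profiles <- function(ds, window = 0, stat = c("mean", "median"),
                          groups = NULL) {
  stat <- match.arg(stat)
  if (is.null(groups)) groups <- setdiff(unique(ds$obs$group), "QC")
  out <- do.call(rbind, lapply(groups, function(g)
    group_trend(ds, g, window = window, stat = stat)))
  class(out) <- c("mtb_profiles", "data.frame")
  out
}

#' Subtract the control group's time trend
#'
#' Removes growth- and environment-related signal shared with the
#' control: the control group's smoothed trend (see [group_trend()]) is
#' subtracted from every experimental observation at its nearest control
#' time point. Control and QC observations are dropped from the result.
#'
#' @param ds an [mtb_dataset()].
#' @param control the control group's label.
#' @param window,stat trend-generation settings (these are independent
#'   of any later profile-generation smoothing).
#' @param time_tol largest allowed gap between an experimental time and
#'   the nearest control time (default: `window`); beyond it the control
#'   coverage is considered missing and an error is raised.
#' @return The control-corrected `mtb_dataset` containing only the
#'   experimental groups.
#' @export
control_correct <- function(ds, control, window = 0,
                            stat = c("mean", "median"), time_tol = window) {
  stopifnot(inherits(ds, "mtb_dataset"))
  stat <- match.arg(stat)
  if (!control %in% ds$obs$group)
    stop("control group '", control, "' not present in the dataset")
  trend <- group_trend(ds, control, window = window, stat = stat)
  ctimes <- sort(unique(trend$time))
  # trend matrix: peaks x control times
  tm <- matrix(NA_real_, ncol(ds$X), length(ctimes),
               dimnames = list(ds$peaks$peak_id, NULL))
  tm[cbind(match(trend$peak_id, ds$peaks$peak_id), match(trend$time, ctimes))] <-
    trend$value
  keep <- ds$obs$group != control & !qc_mask(ds)
  t_exp <- ds$obs$time[keep]
  nearest <- vapply(t_exp, function(tt) which.min(abs(ctimes - tt)), integer(1))
  gap <- abs(ctimes[nearest] - t_exp)
  if (any(gap > time_tol))
    stop("no control trend value within ", time_tol, " time units of t = ",
         paste(unique(t_exp[gap > time_tol]), collapse = ", "))
  Xc <- ds$X[keep, , drop = FALSE] - t(tm[, nearest, drop = FALSE])
  mtb_dataset(Xc, ds$obs[keep, , drop = FALSE], ds$peaks)
}

#' Build clustering input vectors from time profiles
#'
#' The objects clustered downstream are not the raw observations but the
#' per-peak smoothed group profiles. In `concatenated` mode each peak's
#' group profiles are joined end to end (groups in `group_order`) into a
#' single vector; group time grids may differ in length. In `per_group`
#' mode each (peak, group) pair yields its own vector, which requires
#' every group to share one time grid.
#'
#' @param profiles an `mtb_profiles` long data frame (see
#'   [time_profiles()]).
#' @param mode `"concatenated"` or `"per_group"`.
#' @param group_order order in which groups are laid out (default: order
#'   of first appearance).
#' @return An object of class `mtb_vectors`: a numeric matrix with one
#'   labelled row per vector, plus attributes `layout` (data frame
#'   `group`, `time` describing the columns) and `mode`.
#' @export
build_input_vectors <- function(profiles, mode = c("concatenated", "per_group"),
                                group_order = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(c("peak_id", "group", "time", "value") %in% names(profiles)))
  if (is.null(group_order)) group_order <- unique(profiles$group)
  if (!all(profiles$group %in% group_order))
    stop("group_order does not cover group(s): ",
         paste(setdiff(unique(profiles$group), group_order), collapse = ", "))
  peaks <- unique(profiles$peak_id)

  grids <- lapply(group_order, function(g)
    sort(unique(profiles$time[profiles$group == g])))
  names(grids) <- group_order

  # every peak must cover each group's full grid
  cnt <- table(profiles$peak_id, profiles$group)
  want <- vapply(grids, length, integer(1))
  bad <- peaks[apply(cnt[peaks, group_order, drop = FALSE], 1,
                     function(r) any(r != want))]
  if (length(bad) > 0)
    stop("ragged time grids for peak(s): ", paste(bad, collapse = ", "))

  value_block <- function(g) {
    sub <- profiles[profiles$group == g, ]
    m <- matrix(NA_real_, length(peaks), length(grids[[g]]),
                dimnames = list(peaks, NULL))
    m[cbind(match(sub$peak_id, peaks), match(sub$time, grids[[g]]))] <- sub$value
    m
  }

  if (mode == "concatenated") {
    blocks <- lapply(group_order, value_block)
    M <- do.call(cbind, blocks)
    layout <- data.frame(group = rep(group_order, times = want),
                         time = unlist(grids, use.names = FALSE))
  } else {
    if (!all(vapply(grids, identical, logical(1), grids[[1]])))
      stop("per_group mode requires all groups to share one time grid")
    blocks <- lapply(group_order, value_block)
    M <- do.call(rbind, blocks)
    rownames(M) <- as.vector(t(outer(group_order, peaks,
                                     function(g, p) paste(p, g, sep = "::"))))
    layout <- data.frame(group = "*", time = grids[[1]])
  }
  structure(M, layout = layout, mode = mode, class = c("mtb_vectors", "matrix"))
}

#' @export
print.mtb_vectors <- function(x, ...) {
  cat("mtb_vectors: ", nrow(x), " vectors of length ", ncol(x),
      " (mode ", attr(x, "mode"), ")\n", sep = "")
  invisible(x)
}

#' Write time profiles as long-format CSV
#'
#' @param profiles an `mtb_profiles` data frame.
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.csv(as.data.frame(profiles), path, row.names = FALSE)
  invisible(path)
}
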