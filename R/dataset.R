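#' Assemble a peak-intensity dataset
#'
#' Binds an observations x peaks intensity matrix to its observation and
#' peak metadata and validates the result. Quality-control injections are
#' identified by the reserved group label `"QC"` in the observation
#' metadata; all other groups are treated as experimental or control
#' groups. Missing intensities (`NA`) are permitted at this stage and must
#' be imputed (or rejected) before batch correction.
#'
#' @param X numeric matrix, one row per observation and one column per
#'   peak. Row and column names, if present, must agree with the metadata
#'   IDs.
#' @param obs data frame of observation metadata with columns `obs_id`,
#'   `group`, `time`, `batch`, `acq_order`, `replicate`. `time` may be
#'   `NA` for QC injections only; `acq_order` is the integer rank of each
#'   injection in the full run sequence.
#' @param peaks data frame of peak metadata with columns `peak_id`, `mz`,
#'   `rt` and `mode` (`"+"` or `"-"`).
#' @return An object of class `mtb_dataset`: a list with elements `X`,
#'   `obs` and `peaks`.
#' @seealso [load_dataset()] to read the three CSV files,
#'   [simulate_timecourse()] to generate ground-truthed data.
#' @export
mtb_dataset <- function(X, obs, peaks) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  obs <- as.data.frame(obs)
  peaks <- as.data.frame(peaks)

  need_obs <- c("obs_id", "group", "time", "batch", "acq_order", "replicate")
  miss <- setdiff(need_obs, names(obs))
  if (length(miss) > 0)
    stop("observation metadata lacks column(s): ", paste(miss, collapse = ", "))
  need_pk <- c("peak_id", "mz", "rt", "mode")
  miss <- setdiff(need_pk, names(peaks))
  if (length(miss) > 0)
    stop("peak metadata lacks column(s): ", paste(miss, collapse = ", "))

  obs$obs_id <- as.character(obs$obs_id)
  obs$group <- as.character(obs$group)
  obs$batch <- as.character(obs$batch)
  obs$replicate <- as.character(obs$replicate)
  obs$time <- as.numeric(obs$time)
  obs$acq_order <- as.integer(obs$acq_order)
  peaks$peak_id <- as.character(peaks$peak_id)
  peaks$mz <- as.numeric(peaks$mz)
  peaks$rt <- as.numeric(peaks$rt)
  peaks$mode <- as.character(peaks$mode)

  if (anyDuplicated(obs$obs_id))
    stop("duplicate obs_id: ",
         paste(unique(obs$obs_id[duplicated(obs$obs_id)]), collapse = ", "))
  if (anyDuplicated(peaks$peak_id))
    stop("duplicate peak_id: ",
         paste(unique(peaks$peak_id[duplicated(peaks$peak_id)]), collapse = ", "))
  if (anyDuplicated(obs$acq_order))
    stop("acq_order must be unique across the run sequence")
  if (nrow(X) != nrow(obs))
    stop("intensity matrix has ", nrow(X), " rows but metadata describes ",
         nrow(obs), " observations")
  if (ncol(X) != nrow(peaks))
    stop("intensity matrix has ", ncol(X), " columns but metadata describes ",
         nrow(peaks), " peaks")
  if (!is.null(rownames(X)) && !identical(rownames(X), obs$obs_id)) {
    bad <- union(setdiff(rownames(X), obs$obs_id), setdiff(obs$obs_id, rownames(X)))
    if (length(bad) > 0)
      stop("observation IDs disagree between matrix and metadata: ",
           paste(bad, collapse = ", "))
    X <- X[match(obs$obs_id, rownames(X)), , drop = FALSE]
  }
  if (!is.null(colnames(X)) && !identical(colnames(X), peaks$peak_id)) {
    bad <- union(setdiff(colnames(X), peaks$peak_id), setdiff(peaks$peak_id, colnames(X)))
    if (length(bad) > 0)
      stop("peak IDs disagree between matrix and metadata: ",
           paste(bad, collapse = ", "))
    X <- X[, match(peaks$peak_id, colnames(X)), drop = FALSE]
  }
  dimnames(X) <- list(obs$obs_id, peaks$peak_id)

  if (any(is.infinite(X)))
    stop("non-finite (infinite) intensities found")
  non_qc <- obs$group != "QC"
  if (any(non_qc & is.na(obs$time)))
    stop("time missing for non-QC observation(s): ",
         paste(obs$obs_id[non_qc & is.na(obs$time)], collapse = ", "))
  if (any(!is.finite(peaks$mz) | peaks$mz <= 0))
    stop("mz must be finite and > 0 for all peaks")

  structure(list(X = X, obs = obs, peaks = peaks), class = "mtb_dataset")
}

#' @export
print.mtb_dataset <- function(x, ...) {
  grp <- table(x$obs$group)
  cat("mtb_dataset: ", nrow(x$X), " observations x ", ncol(x$X), " peaks\n", sep = "")
  cat("  groups: ", paste(names(grp), " (", grp, ")", sep = "", collapse = ", "), "\n", sep = "")
  cat("  batches: ", paste(unique(x$obs$batch), collapse = ", "), "\n", sep = "")
  nmiss <- sum(is.na(x$X))
  if (nmiss > 0) cat("  missing intensities: ", nmiss, "\n", sep = "")
  invisible(x)
}

#' @export
dim.mtb_dataset <- function(x) dim(x$X)

#' Read a dataset from its three CSV files
#'
#' The intensity file holds one observation per row and one variable
#' (peak) per column: the first column carries observation IDs and the
#' header row carries peak IDs. Blank or `NA` cells are imported as
#' missing values, never as zeros. All files are UTF-8,
#' comma-separated, decimal point.
#'
#' @param intensity_path,obs_meta_path,peak_meta_path paths to the
#'   intensity matrix, observation metadata and peak metadata CSVs.
#' @return An [mtb_dataset()].
#' @export
load_dataset <- function(intensity_path, obs_meta_path, peak_meta_path) {
  for (p in c(intensity_path, obs_meta_path, peak_meta_path))
    if (!file.exists(p)) stop("file not found: ", p)
  raw <- utils::read.csv(intensity_path, check.names = FALSE,
                         stringsAsFactors = FALSE, na.strings = c("NA", ""))
  X <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- as.character(raw[[1]])
  obs <- utils::read.csv(obs_meta_path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  peaks <- utils::read.csv(peak_meta_path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  mtb_dataset(X, obs, peaks)
}

#' Write a dataset to its three CSV files
#'
#' Inverse of [load_dataset()]: writes `intensity.csv`, `observations.csv`
#' and `peaks.csv` under `dir` such that reloading reproduces the dataset
#' field for field.
#'
#' @param ds an [mtb_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "mtb_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ip <- file.path(dir, "intensity.csv")
  op <- file.path(dir, "observations.csv")
  pp <- file.path(dir, "peaks.csv")
  df <- data.frame(obs_id = rownames(ds$X), ds$X, check.names = FALSE)
  utils::write.csv(df, ip, row.names = FALSE, quote = FALSE)
  utils::write.csv(ds$obs, op, row.names = FALSE, quote = FALSE)
  utils::write.csv(ds$peaks, pp, row.names = FALSE, quote = FALSE)
  invisible(c(intensity = ip, observations = op, peaks = pp))
}

#' Subset a dataset to selected peaks and/or observations
#'
#' @param ds an [mtb_dataset()].
#' @param peaks character vector of peak IDs or logical/integer index.
#' @param obs character vector of observation IDs or logical/integer index.
#' @return The subsetted `mtb_dataset`.
#' @export
subset_dataset <- function(ds, peaks = NULL, obs = NULL) {
  stopifnot(inherits(ds, "mtb_dataset"))
  pi <- seq_len(ncol(ds$X))
  oi <- seq_len(nrow(ds$X))
  if (!is.null(peaks)) {
    pi <- if (is.character(peaks)) match(peaks, ds$peaks$peak_id) else which(rep(TRUE, ncol(ds$X)))[peaks]
    if (anyNA(pi)) stop("unknown peak_id in subset")
  }
  if (!is.null(obs)) {
    oi <- if (is.character(obs)) match(obs, ds$obs$obs_id) else which(rep(TRUE, nrow(ds$X)))[obs]
    if (anyNA(oi)) stop("unknown obs_id in subset")
  }
  mtb_dataset(ds$X[oi, pi, drop = FALSE], ds$obs[oi, , drop = FALSE],
              ds$peaks[pi, , drop = FALSE])
}

qc_mask <- function(ds) ds$obs$group == "QC"
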