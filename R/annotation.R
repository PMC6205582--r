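#' Expected m/z of a compound under an adduct
#'
#' `m/z = (n * M + mass_shift) / |z|` for a neutral monoisotopic mass M
#' (Da), multimer count n, charge z and electron-corrected mass shift
#' (Da). For example [M+H]+ has n = 1, z = +1, shift +1.007276 (a proton).
#'
#' @param monoisotopic_mass neutral monoisotopic mass in Da (> 0).
#' @param adduct a one-row data frame (or list) with `n`, `charge`,
#'   `mass_shift`.
#' @return The expected m/z in Da.
#' @export
expected_mz <- function(monoisotopic_mass, adduct) {
  n <- adduct$n
  z <- adduct$charge
  shift <- adduct$mass_shift
  if (any(monoisotopic_mass <= 0)) stop("monoisotopic_mass must be > 0")
  if (any(z == 0)) stop("adduct charge must be nonzero")
  (n * monoisotopic_mass + shift) / abs(z)
}

#' Putative accurate-mass annotation of peaks
#'
#' Matches every peak's observed m/z against the expected m/z of every
#' (compound, adduct) pair with the peak's ionization polarity (adduct
#' polarity is the sign of its charge). Every pair within `tol_ppm` is
#' reported — a peak may carry several annotations and a compound may
#' match several peaks; no best-match pruning is performed. Annotations
#' by accurate mass alone are the lowest identification confidence tier
#' and are labelled "putative (MSI level 5)".
#'
#' @param peaks data frame of peak metadata (`peak_id`, `mz`, `mode`) or
#'   an [mtb_dataset()].
#' @param kb an [mtb_knowledge_base()].
#' @param tol_ppm mass tolerance in parts per million (default 5).
#' @return Data frame of class `mtb_annotations`: `peak_id`,
#'   `compound_id`, `compound_name`, `adduct`, `expected_mz`,
#'   `observed_mz`, `error_ppm` (signed), `confidence`.
#' @export
annotate_peaks <- function(peaks, kb, tol_ppm = 5) {
  if (inherits(peaks, "mtb_dataset")) peaks <- peaks$peaks
  stopifnot(inherits(kb, "mtb_kb"), tol_ppm >= 0)
  empty <- data.frame(peak_id = character(0), compound_id = character(0),
                      compound_name = character(0), adduct = character(0),
                      expected_mz = numeric(0), observed_mz = numeric(0),
                      error_ppm = numeric(0), confidence = character(0))
  class(empty) <- c("mtb_annotations", "data.frame")
  if (nrow(kb$compounds) == 0 || nrow(kb$adducts) == 0 || nrow(peaks) == 0)
    return(empty)

  # all (compound, adduct) expected m/z values, tagged with polarity
  grid <- expand.grid(ci = seq_len(nrow(kb$compounds)),
                      ai = seq_len(nrow(kb$adducts)))
  exp_mz <- (kb$adducts$n[grid$ai] * kb$compounds$monoisotopic_mass[grid$ci] +
               kb$adducts$mass_shift[grid$ai]) / abs(kb$adducts$charge[grid$ai])
  pol <- ifelse(kb$adducts$charge[grid$ai] > 0, "+", "-")

  out <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    ok <- pol == peaks$mode[i]
    err <- 1e6 * (peaks$mz[i] - exp_mz) / exp_mz
    hit <- which(ok & abs(err) <= tol_ppm)
    if (length(hit) == 0) next
    out[[i]] <- data.frame(
      peak_id = peaks$peak_id[i],
      compound_id = kb$compounds$compound_id[grid$ci[hit]],
      compound_name = kb$compounds$name[grid$ci[hit]],
      adduct = kb$adducts$name[grid$ai[hit]],
      expected_mz = exp_mz[hit],
      observed_mz = peaks$mz[i],
      error_ppm = err[hit],
      confidence = "putative (MSI level 5)")
  }
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  class(res) <- c("mtb_annotations", "data.frame")
  res
}

#' Cluster-pathway overlap table
#'
#' For every (cluster, pathway) pair, counts the annotated peaks of the
#' cluster whose putative compounds belong to the pathway (`n_peaks`)
#' and the distinct member compounds those annotations cover
#' (`n_compounds`, never exceeding the pathway's size). Because several
#' peaks may represent one compound (adducts, in-source fragments),
#' `n_peaks` can exceed `n_compounds`. Rows are sorted by `n_peaks`
#' descending, then `n_compounds` descending, then `pathway_id`.
#'
#' @param model a [dkmeanspp()] model whose vector labels are peak IDs
#'   (or `peak::group` labels).
#' @param annotations an `mtb_annotations` data frame from
#'   [annotate_peaks()].
#' @param kb an [mtb_knowledge_base()].
#' @return Data frame of class `mtb_overlap`: `cluster_id`,
#'   `pathway_id`, `pathway_name`, `n_peaks`, `n_compounds`,
#'   `compounds` (semicolon-joined names).
#' @export
pathway_overlap <- function(model, annotations, kb) {
  stopifnot(inherits(model, "dkmeanspp"), inherits(kb, "mtb_kb"))
  pid <- sub("::.*$", "", names(model$cluster))
  pwy_ids <- unique(kb$pathways$pathway_id)
  clusters <- sort(unique(as.integer(model$cluster)))
  rows <- list()
  for (cl in clusters) {
    cl_peaks <- unique(pid[model$cluster == cl])
    ann <- annotations[annotations$peak_id %in% cl_peaks, , drop = FALSE]
    for (pw in pwy_ids) {
      members <- kb$pathways$compound_id[kb$pathways$pathway_id == pw]
      hit <- ann[ann$compound_id %in% members, , drop = FALSE]
      cmp <- unique(hit$compound_id)
      nm <- kb$compounds$name[match(cmp, kb$compounds$compound_id)]
      rows[[length(rows) + 1]] <- data.frame(
        cluster_id = cl,
        pathway_id = pw,
        pathway_name = kb$pathways$name[match(pw, kb$pathways$pathway_id)],
        n_peaks = length(unique(hit$peak_id)),
        n_compounds = length(cmp),
        compounds = paste(sort(nm), collapse = ";"),
        compound_ids = paste(sort(cmp), collapse = ";"))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(cluster_id = integer(0), pathway_id = character(0),
                  pathway_name = character(0), n_peaks = integer(0),
                  n_compounds = integer(0), compounds = character(0),
                  compound_ids = character(0))
  out <- out[order(-out$n_peaks, -out$n_compounds, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mtb_overlap", "data.frame")
  out
}

#' Export per-(cluster, pathway) compound lists
#'
#' Writes one plain-text file per (cluster, pathway) pair with
#' `n_compounds > 0`, one compound ID per line — the paste-in format
#' accepted by MetaCyc SmartTables and similar pathway tools.
#'
#' @param overlaps an `mtb_overlap` table from [pathway_overlap()].
#' @param kb the [mtb_knowledge_base()] used to build it.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the written file paths (possibly none).
#' @export
export_pathway_lists <- function(overlaps, kb, out_dir) {
  stopifnot(inherits(overlaps, "mtb_overlap"), inherits(kb, "mtb_kb"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sel <- overlaps[overlaps$n_compounds > 0, , drop = FALSE]
  paths <- character(0)
  for (i in seq_len(nrow(sel))) {
    ids <- strsplit(sel$compound_ids[i], ";", fixed = TRUE)[[1]]
    safe <- gsub("[^A-Za-z0-9._-]", "_", sel$pathway_id[i])
    p <- file.path(out_dir, paste0("cluster", sel$cluster_id[i], "_", safe, ".txt"))
    writeLines(sort(ids), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write annotations as CSV
#'
#' @param annotations an `mtb_annotations` data frame.
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(as.data.frame(annotations), path, row.names = FALSE)
  invisible(path)
}
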