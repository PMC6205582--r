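#' Assemble a compound / adduct / pathway knowledge base
#'
#' The knowledge base drives accurate-mass annotation and pathway overlap
#' scoring: compounds carry monoisotopic masses (Da), adducts carry the
#' multimer count n, charge z and mass shift (Da, electron-corrected) of
#' each ion form, and pathways are long-format memberships
#' (pathway_id, compound_id).
#'
#' @param compounds data frame with columns `compound_id`, `name`,
#'   `monoisotopic_mass`.
#' @param adducts data frame with columns `name`, `n` (multimer count,
#'   >= 1), `charge` (nonzero integer) and `mass_shift` (Da).
#' @param pathways data frame with columns `pathway_id`, `compound_id`
#'   and optionally `name`; may have zero rows.
#' @return An object of class `mtb_kb`.
#' @export
mtb_knowledge_base <- function(compounds, adducts, pathways) {
  compounds <- as.data.frame(compounds)
  adducts <- as.data.frame(adducts)
  pathways <- as.data.frame(pathways)

  for (col in c("compound_id", "name", "monoisotopic_mass"))
    if (!col %in% names(compounds)) stop("compound table lacks column ", col)
  for (col in c("name", "n", "charge", "mass_shift"))
    if (!col %in% names(adducts)) stop("adduct table lacks column ", col)
  if (nrow(pathways) > 0)
    for (col in c("pathway_id", "compound_id"))
      if (!col %in% names(pathways)) stop("pathway table lacks column ", col)
  if (!"name" %in% names(pathways))
    pathways$name <- if (nrow(pathways)) as.character(pathways$pathway_id) else character(0)

  compounds$compound_id <- as.character(compounds$compound_id)
  compounds$monoisotopic_mass <- as.numeric(compounds$monoisotopic_mass)
  if (anyDuplicated(compounds$compound_id))
    stop("duplicate compound_id: ",
         paste(unique(compounds$compound_id[duplicated(compounds$compound_id)]),
               collapse = ", "))
  if (any(!is.finite(compounds$monoisotopic_mass) | compounds$monoisotopic_mass <= 0))
    stop("monoisotopic_mass must be finite and > 0")
  adducts$n <- as.integer(adducts$n)
  adducts$charge <- as.integer(adducts$charge)
  adducts$mass_shift <- as.numeric(adducts$mass_shift)
  if (any(adducts$n < 1)) stop("adduct multimer count n must be >= 1")
  if (any(adducts$charge == 0)) stop("adduct charge must be nonzero")
  if (nrow(pathways) > 0) {
    pathways$pathway_id <- as.character(pathways$pathway_id)
    pathways$compound_id <- as.character(pathways$compound_id)
    unknown <- setdiff(pathways$compound_id, compounds$compound_id)
    if (length(unknown) > 0)
      stop("pathway member(s) reference unknown compound_id: ",
           paste(unknown, collapse = ", "))
  }

  structure(list(compounds = compounds, adducts = adducts, pathways = pathways),
            class = "mtb_kb")
}

#' @export
print.mtb_kb <- function(x, ...) {
  cat("mtb_kb: ", nrow(x$compounds), " compounds, ", nrow(x$adducts),
      " adducts, ", length(unique(x$pathways$pathway_id)), " pathways\n", sep = "")
  invisible(x)
}

#' Read a knowledge base from its three CSV files
#'
#' @param compound_path CSV with `compound_id,name,monoisotopic_mass`.
#' @param adduct_path CSV with `name,n,charge,mass_shift`.
#' @param pathway_path long-format CSV with `pathway_id,compound_id`
#'   (optionally `name`); may contain only the header.
#' @return An [mtb_knowledge_base()].
#' @export
load_knowledge_base <- function(compound_path, adduct_path, pathway_path) {
  for (p in c(compound_path, adduct_path, pathway_path))
    if (!file.exists(p)) stop("file not found: ", p)
  compounds <- utils::read.csv(compound_path, stringsAsFactors = FALSE)
  adducts <- utils::read.csv(adduct_path, stringsAsFactors = FALSE)
  pathways <- utils::read.csv(pathway_path, stringsAsFactors = FALSE)
  mtb_knowledge_base(compounds, adducts, pathways)
}

#' Write a knowledge base to its three CSV files
#'
#' @param kb an [mtb_knowledge_base()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_knowledge_base <- function(kb, dir) {
  stopifnot(inherits(kb, "mtb_kb"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cp <- file.path(dir, "compounds.csv")
  ap <- file.path(dir, "adducts.csv")
  pp <- file.path(dir, "pathways.csv")
  utils::write.csv(kb$compounds, cp, row.names = FALSE, quote = FALSE)
  utils::write.csv(kb$adducts, ap, row.names = FALSE, quote = FALSE)
  utils::write.csv(kb$pathways, pp, row.names = FALSE, quote = FALSE)
  invisible(c(compounds = cp, adducts = ap, pathways = pp))
}

#' Convert PathwayTools/BioCyc flat-file dumps to the long-format CSVs
#'
#' Reads the attribute-value flat files exported by PathwayTools-style
#' databases (records separated by `//`, lines of the form
#' `ATTRIBUTE - VALUE`). Compounds are taken from records carrying
#' `UNIQUE-ID` and `MONOISOTOPIC-MW`; pathway membership from pathway
#' records' `COMPOUND-LIST` (or `MEMBERS`) attributes.
#'
#' @param compounds_dat path to the compounds flat file.
#' @param pathways_dat path to the pathways flat file.
#' @param out_dir directory receiving `compounds.csv` and `pathways.csv`.
#' @return Invisibly, the two output paths.
#' @export
biocyc_to_csv <- function(compounds_dat, pathways_dat, out_dir) {
  parse_records <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "#")]
    recs <- split(lines, cumsum(lines == "//"))
    lapply(recs, function(r) {
      r <- r[r != "//" & grepl(" - ", r, fixed = TRUE)]
      key <- sub(" - .*$", "", r)
      val <- sub("^[^ ]+ - ", "", r)
      split(val, key)
    })
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cmp <- parse_records(compounds_dat)
  rows <- lapply(cmp, function(r) {
    if (is.null(r[["UNIQUE-ID"]]) || is.null(r[["MONOISOTOPIC-MW"]])) return(NULL)
    data.frame(compound_id = r[["UNIQUE-ID"]][1],
               name = if (!is.null(r[["COMMON-NAME"]])) r[["COMMON-NAME"]][1] else r[["UNIQUE-ID"]][1],
               monoisotopic_mass = as.numeric(r[["MONOISOTOPIC-MW"]][1]))
  })
  compounds <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  pwy <- parse_records(pathways_dat)
  rows <- lapply(pwy, function(r) {
    if (is.null(r[["UNIQUE-ID"]])) return(NULL)
    members <- c(r[["COMPOUND-LIST"]], r[["MEMBERS"]])
    if (length(members) == 0) return(NULL)
    data.frame(pathway_id = r[["UNIQUE-ID"]][1],
               compound_id = members,
               name = if (!is.null(r[["COMMON-NAME"]])) r[["COMMON-NAME"]][1] else r[["UNIQUE-ID"]][1])
  })
  pathways <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(pathways))
    pathways <- data.frame(pathway_id = character(0), compound_id = character(0),
                           name = character(0))
  # drop memberships whose compound has no monoisotopic mass record
  pathways <- pathways[pathways$compound_id %in% compounds$compound_id, , drop = FALSE]
  cp <- file.path(out_dir, "compounds.csv")
  pp <- file.path(out_dir, "pathways.csv")
  utils::write.csv(compounds, cp, row.names = FALSE, quote = FALSE)
  utils::write.csv(pathways, pp, row.names = FALSE, quote = FALSE)
  invisible(c(compounds = cp, pathways = pp))
}
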