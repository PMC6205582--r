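#' Run the full analysis pipeline from a config
#'
#' Executes the stages in fixed order — import, batch correction,
#' scaling, profile generation (control correction + input vectors),
#' significance filtering, clustering, annotation, pathway overlap —
#' writing each stage's CSV/JSON outputs under the configured output
#' directory together with a manifest (config with defaults filled,
#' package version, per-stage fingerprint and dimensions). Every stage
#' except import and cluster is optional.
#'
#' Each stage's outputs are fingerprinted from its configuration plus
#' everything upstream (for the import stage, the input files' md5
#' sums). Rerunning with an unchanged upstream configuration leaves the
#' cached files untouched on disk — only stages whose fingerprint
#' changed are rewritten — so runs are restartable and byte-stable.
#'
#' @param config path to a YAML config file, or an equivalent named
#'   list. See the package vignette for the schema; minimally:
#'   `input:` (paths `intensity`, `observations`, `peaks`, and for
#'   annotation `compounds`, `adducts`, `pathways`), `output:` (a
#'   directory) and a `cluster:` block with `k` and/or `d_stop`.
#' @param force recompute and rewrite every stage, ignoring the cache.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results
#'   (`dataset`, `vectors`, `filter`, `model`, `annotations`,
#'   `overlaps`, `manifest`).
#' @export
run_pipeline <- function(config, force = FALSE, quiet = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- fill_config_defaults(cfg)
  out_dir <- cfg$output
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log_path, append = TRUE)
    if (!quiet) message(msg)
  }
  manifest <- list(config = cfg,
                   package_version = as.character(utils::packageVersion("metabotrend")),
                   stages = list())
  stage_dir <- function(name) {
    d <- file.path(out_dir, name)
    if (!dir.exists(d)) dir.create(d)
    d
  }
  # returns TRUE when the stage's cached outputs are current
  cached <- function(name, fp) {
    stage_dir(name)
    f <- file.path(out_dir, name, ".fingerprint")
    ok <- !force && file.exists(f) && identical(readLines(f, warn = FALSE), fp)
    if (!ok) writeLines(fp, f) else log("stage ", name, ": cached (", fp, ")")
    ok
  }
  abort <- function(name, e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         " (partial outputs retained in ", out_dir, ")", call. = FALSE)

  # import -------------------------------------------------------------
  fp <- md5_obj(list(unname(tools::md5sum(unlist(cfg$input[c(
    "intensity", "observations", "peaks")]))), cfg$input))
  ds <- tryCatch(load_dataset(cfg$input$intensity, cfg$input$observations,
                              cfg$input$peaks),
                 error = function(e) abort("import", e))
  kb <- NULL
  if (!is.null(cfg$input$compounds))
    kb <- tryCatch(load_knowledge_base(cfg$input$compounds, cfg$input$adducts,
                                       cfg$input$pathways),
                   error = function(e) abort("import", e))
  manifest$stages$import <- list(fingerprint = fp, rows = nrow(ds$X),
                                 cols = ncol(ds$X))
  log("import: ", nrow(ds$X), " observations x ", ncol(ds$X), " peaks")

  # correct ------------------------------------------------------------
  if (!is.null(cfg$correct)) {
    sc <- cfg$correct
    fp <- md5_obj(list(fp, sc))
    d <- stage_dir("correct")
    before <- tryCatch(impute_missing(ds, quiet = TRUE),
                       error = function(e) abort("correct", e))
    cf <- tryCatch(correction_factors(before, method = sc$method,
                                      window = sc$window, rescale = sc$rescale,
                                      form = sc$form),
                   error = function(e) abort("correct", e))
    ds <- apply_correction(before, cf)
    if (!cached("correct", fp)) {
      write_dataset(ds, d)
      q <- correction_quality(before, ds)
      write_quality_report(q, file.path(d, "quality.csv"))
    }
    manifest$stages$correct <- list(fingerprint = fp, method = sc$method)
    log("correct: method ", sc$method, " (", sc$form, ")")
  } else ds <- impute_missing(ds, quiet = TRUE)

  # scale --------------------------------------------------------------
  if (!is.null(cfg$scale)) {
    sc <- cfg$scale
    fp <- md5_obj(list(fp, sc))
    ds <- tryCatch(
      withCallingHandlers(
        scale_peaks(ds, method = sc$method, center = sc$center),
        warning = function(w) {
          log("scale: ", conditionMessage(w)); invokeRestart("muffleWarning")
        }),
      error = function(e) abort("scale", e))
    if (!cached("scale", fp)) write_dataset(ds, stage_dir("scale"))
    manifest$stages$scale <- list(fingerprint = fp, method = sc$method,
                                  peaks = ncol(ds$X))
    log("scale: ", sc$method, ", ", ncol(ds$X), " peaks retained")
  }

  # filter p-values come from the data while the control is still present
  filter_input <- ds

  # profiles ------------------------------------------------------------
  sc <- cfg$profiles
  fp <- md5_obj(list(fp, sc))
  ds_p <- ds
  if (!is.null(sc$control))
    ds_p <- tryCatch(control_correct(ds, control = sc$control,
                                     window = sc$control_window,
                                     stat = sc$control_stat),
                     error = function(e) abort("profiles", e))
  profs <- tryCatch(time_profiles(ds_p, window = sc$window, stat = sc$stat),
                    error = function(e) abort("profiles", e))
  vectors <- tryCatch(build_input_vectors(profs, mode = sc$vector_mode,
                                          group_order = sc$group_order),
                      error = function(e) abort("profiles", e))
  if (!cached("profiles", fp))
    write_profiles(profs, file.path(stage_dir("profiles"), "profiles.csv"))
  manifest$stages$profiles <- list(fingerprint = fp,
                                   vectors = nrow(vectors),
                                   length = ncol(vectors))
  log("profiles: ", nrow(vectors), " input vectors of length ", ncol(vectors))

  # filter --------------------------------------------------------------
  filt <- NULL
  if (!is.null(cfg$filter)) {
    sc <- cfg$filter
    fp <- md5_obj(list(fp, sc))
    filt <- tryCatch({
      f <- significance_filter(filter_input, control = cfg$profiles$control,
                               alpha = sc$alpha %||% 0.05)
      if (!is.null(sc$labels)) {
        lab <- utils::read.csv(sc$labels, stringsAsFactors = FALSE)
        opt <- optimize_alpha(
          f$table$p_min[match(lab$peak_id, f$table$peak_id)], lab$label)
        log("filter: optimized alpha = ", opt$alpha, " (match rate ",
            round(opt$match_rate, 3), ")")
        f <- significance_filter(filter_input, control = cfg$profiles$control,
                                 alpha = opt$alpha)
      }
      f
    }, error = function(e) abort("filter", e))
    vectors <- apply_filter(vectors, filt)
    if (!cached("filter", fp))
      write_filter(filt, file.path(stage_dir("filter"), "filter.csv"))
    manifest$stages$filter <- list(fingerprint = fp, alpha = filt$alpha,
                                   retained = sum(filt$table$included))
    log("filter: alpha ", filt$alpha, ", ", sum(filt$table$included), " / ",
        nrow(filt$table), " peaks retained")
  } else log("filter: stage omitted; all peaks proceed to clustering")

  # cluster --------------------------------------------------------------
  sc <- cfg$cluster
  fp <- md5_obj(list(fp, sc))
  model <- tryCatch(
    dkmeanspp(vectors, k = sc$k, D_stop = sc$d_stop,
              seed_method = sc$seed_method, update = sc$update),
    error = function(e) abort("cluster", e))
  baseline <- NULL
  if (!is.null(sc$baseline_runs) && sc$baseline_runs > 0)
    baseline <- kmeans_baseline(vectors, k = model$k, runs = sc$baseline_runs,
                                rng_seed = cfg$seed)
  if (!cached("cluster", fp)) {
    d <- stage_dir("cluster")
    write_cluster_model(model, d)
    grDevices::png(file.path(d, "clusters.png"), width = 1200, height = 1200)
    plot(model)
    grDevices::dev.off()
  }
  manifest$stages$cluster <- list(fingerprint = fp, k = model$k,
                                  D = unname(model$metrics[["D"]]))
  log("cluster: k = ", model$k, ", D = ", signif(model$metrics[["D"]], 4),
      if (!is.null(baseline))
        paste0(" (baseline D = ", signif(baseline$metrics[["D"]], 4), ")"))

  # annotate -------------------------------------------------------------
  ann <- NULL
  if (!is.null(cfg$annotate)) {
    if (is.null(kb)) abort("annotate", simpleError("no knowledge base loaded"))
    sc <- cfg$annotate
    fp <- md5_obj(list(fp, sc))
    ann <- annotate_peaks(ds$peaks, kb, tol_ppm = sc$tol_ppm)
    if (!cached("annotate", fp))
      write_annotations(ann, file.path(stage_dir("annotate"), "annotations.csv"))
    manifest$stages$annotate <- list(fingerprint = fp, annotations = nrow(ann))
    log("annotate: ", nrow(ann), " putative annotations at ", sc$tol_ppm, " ppm")
  }

  # pathways -------------------------------------------------------------
  ovl <- NULL
  if (!is.null(cfg$pathways)) {
    if (is.null(ann)) abort("pathways", simpleError("annotate stage required"))
    fp <- md5_obj(list(fp, cfg$pathways))
    ovl <- pathway_overlap(model, ann, kb)
    if (!cached("pathways", fp)) {
      d <- stage_dir("pathways")
      utils::write.csv(as.data.frame(ovl), file.path(d, "overlap.csv"),
                       row.names = FALSE)
      export_pathway_lists(ovl, kb, file.path(d, "compound_lists"))
    }
    manifest$stages$pathways <- list(fingerprint = fp,
                                     nonzero = sum(ovl$n_compounds > 0))
    log("pathways: ", sum(ovl$n_compounds > 0),
        " (cluster, pathway) pairs with compounds")
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dataset = ds, vectors = vectors, filter = filt,
                 model = model, baseline = baseline, annotations = ann,
                 overlaps = ovl, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fill_config_defaults <- function(cfg) {
  if (is.null(cfg$input)) stop("config lacks an 'input' block")
  if (is.null(cfg$output)) stop("config lacks an 'output' directory")
  if (is.null(cfg$cluster) ||
      (is.null(cfg$cluster$k) && is.null(cfg$cluster$d_stop)))
    stop("config needs a 'cluster' block with k and/or d_stop")
  cfg$seed <- cfg$seed %||% 1L
  if (!is.null(cfg$correct)) {
    cfg$correct$method <- cfg$correct$method %||% "qc_mean"
    cfg$correct$form <- cfg$correct$form %||% "additive"
    # window/rescale keep correction_factors' own defaults when NULL
  }
  if (!is.null(cfg$scale)) {
    cfg$scale$method <- cfg$scale$method %||% "auto"
    cfg$scale$center <- cfg$scale$center %||% TRUE
  }
  cfg$profiles <- cfg$profiles %||% list()
  cfg$profiles$window <- cfg$profiles$window %||% 0
  cfg$profiles$stat <- cfg$profiles$stat %||% "median"
  cfg$profiles$control_window <- cfg$profiles$control_window %||%
    cfg$profiles$window
  cfg$profiles$control_stat <- cfg$profiles$control_stat %||%
    cfg$profiles$stat
  cfg$profiles$vector_mode <- cfg$profiles$vector_mode %||% "concatenated"
  if (!is.null(cfg$filter)) cfg$filter$alpha <- cfg$filter$alpha %||% 0.05
  cfg$cluster$seed_method <- cfg$cluster$seed_method %||% "max_dist_from_mean"
  cfg$cluster$update <- cfg$cluster$update %||% "mean"
  if (!is.null(cfg$annotate)) cfg$annotate$tol_ppm <- cfg$annotate$tol_ppm %||% 5
  cfg
}

# md5 fingerprint of an arbitrary R object (via a serialized temp file)
md5_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
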