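#' Specification of a synthetic multi-batch LC-MS time course
#'
#' Describes the simulated study design: experimental groups measured
#' daily with replicates, injections split over analytical batches with
#' an additive offset and a linear acquisition-order drift per batch,
#' and a pooled QC injected after every `qc_every`-th sample. Peaks are
#' assigned trend templates (flat, linear, quadratic bump, step —
#' applied to the experimental groups; the control group stays flat), a
#' subset of peaks is placed exactly at the expected m/z of known
#' compound/adduct pairs, and compounds are organised into pathways by
#' template, so batch correction, trend generation, filtering,
#' clustering, annotation and pathway overlap can all be checked against
#' ground truth.
#'
#' Defaults mirror a four-group daily design: control plus three stress
#' groups, days 1-13, 3 replicates per (group, day), 2 batches, a QC
#' every 6th sample, baseline intensity 100, template amplitude 10 and
#' noise SD 0.5.
#'
#' @param n_peaks number of peaks.
#' @param groups group labels; the first is the control group.
#' @param times time grid (e.g. days).
#' @param replicates replicates per (group, time).
#' @param n_batches number of analytical batches (contiguous injection
#'   blocks).
#' @param batch_offsets additive intensity offset per batch (recycled to
#'   `n_batches`); may also be an `n_batches x n_peaks` matrix for
#'   peak-specific offsets.
#' @param drift linear drift slope per batch, in intensity units per
#'   injection (recycled).
#' @param qc_every one pooled QC after every this many samples.
#' @param noise_sd Gaussian noise SD (intensity units).
#' @param noise one of `"additive"` (Gaussian on the intensity scale) or
#'   `"lognormal"` (multiplicative, for multiplicative-form correction
#'   tests; `noise_sd` is then the log-scale SD).
#' @param baseline per-peak baseline intensity (scalar or length
#'   `n_peaks`).
#' @param amplitude template amplitude (intensity units).
#' @param n_templates number of distinct trend templates cycled over the
#'   peaks (2-5; template 1 is always flat/null).
#' @param annotated_fraction fraction of peaks placed exactly at a known
#'   compound/adduct m/z.
#' @param seed integer RNG seed; the whole simulation is a deterministic
#'   function of the spec.
#' @return An object of class `mtb_sim_spec`.
#' @export
simulation_spec <- function(n_peaks = 200,
                            groups = c("control", "drought", "fusarium", "dual"),
                            times = 1:13,
                            replicates = 3,
                            n_batches = 2,
                            batch_offsets = c(0, 5),
                            drift = 0,
                            qc_every = 6,
                            noise_sd = 0.5,
                            noise = c("additive", "lognormal"),
                            baseline = 100,
                            amplitude = 10,
                            n_templates = 5,
                            annotated_fraction = 0.5,
                            seed = 1) {
  noise <- match.arg(noise)
  stopifnot(n_peaks >= 1, length(groups) >= 2, length(times) >= 1,
            replicates >= 1, n_batches >= 1, qc_every >= 1,
            noise_sd >= 0, n_templates >= 2, n_templates <= 5,
            annotated_fraction >= 0, annotated_fraction <= 1)
  if (anyDuplicated(groups)) stop("duplicate group labels")
  if ("QC" %in% groups) stop("'QC' is reserved for quality-control injections")
  if (is.matrix(batch_offsets)) {
    if (nrow(batch_offsets) != n_batches || ncol(batch_offsets) != n_peaks)
      stop("batch_offsets matrix must be n_batches x n_peaks")
  } else batch_offsets <- rep_len(batch_offsets, n_batches)
  drift <- rep_len(drift, n_batches)
  baseline <- rep_len(baseline, n_peaks)
  structure(list(n_peaks = n_peaks, groups = groups, times = times,
                 replicates = replicates, n_batches = n_batches,
                 batch_offsets = batch_offsets, drift = drift,
                 qc_every = qc_every, noise_sd = noise_sd, noise = noise,
                 baseline = baseline, amplitude = amplitude,
                 n_templates = n_templates,
                 annotated_fraction = annotated_fraction, seed = seed),
            class = "mtb_sim_spec")
}

# template value for template id k, group g (index among experimental
# groups; 0 = control), scaled time s in [0, 1]
template_value <- function(k, g_idx, s, amplitude) {
  if (k == 1 || g_idx == 0) return(0)
  # each template perturbs the experimental group(s) congruent to it
  fam <- switch(k, NULL, "linear", "quadratic", "step", "mixed")
  if (fam == "linear") return(amplitude * s)
  if (fam == "quadratic") return(amplitude * 4 * s * (1 - s))
  if (fam == "step") return(amplitude * as.numeric(s >= 0.5))
  # mixed: down-going linear in odd groups, step in even ones
  if (g_idx %% 2 == 1) -amplitude * s else amplitude * as.numeric(s >= 0.5)
}

#' Simulate a ground-truthed multi-batch time-course dataset
#'
#' Generates intensities as
#' `baseline + template(group, time) + batch offset + drift * order +
#' noise`; pooled QC injections carry the grand mean of the template
#' signal over all groups and times (plus the same batch offset, drift
#' and noise), mimicking a pooled QC mixed from the whole study.
#' Injection order is randomized over samples, split contiguously into
#' batches, with a QC inserted after every `qc_every`-th sample.
#'
#' @param spec an [simulation_spec()].
#' @return List with `dataset` (an [mtb_dataset()]), `kb` (an
#'   [mtb_knowledge_base()]) and `truth` (per-peak template IDs, the
#'   offset matrix, drift slopes and true annotations).
#' @export
simulate_timecourse <- function(spec) {
  stopifnot(inherits(spec, "mtb_sim_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  groups <- spec$groups
  control <- groups[1]
  exp_groups <- groups[-1]
  p <- spec$n_peaks
  template_id <- (seq_len(p) - 1L) %% spec$n_templates + 1L

  offsets <- if (is.matrix(spec$batch_offsets)) spec$batch_offsets
             else matrix(spec$batch_offsets, spec$n_batches, p)

  # sample table and injection sequence -------------------------------
  samples <- expand.grid(replicate = paste0("r", seq_len(spec$replicates)),
                         time = spec$times, group = groups,
                         stringsAsFactors = FALSE)
  samples <- samples[sample.int(nrow(samples)), , drop = FALSE]
  ns <- nrow(samples)
  batch_of_sample <- rep(seq_len(spec$n_batches),
                         each = ceiling(ns / spec$n_batches))[seq_len(ns)]

  rows <- list()
  qc_count <- 0L
  for (i in seq_len(ns)) {
    rows[[length(rows) + 1]] <- data.frame(
      group = samples$group[i], time = samples$time[i],
      batch = paste0("b", batch_of_sample[i]),
      replicate = samples$replicate[i])
    if (i %% spec$qc_every == 0) {
      qc_count <- qc_count + 1L
      rows[[length(rows) + 1]] <- data.frame(
        group = "QC", time = NA_real_,
        batch = paste0("b", batch_of_sample[i]),
        replicate = paste0("qc", qc_count))
    }
  }
  obs <- do.call(rbind, rows)
  obs$acq_order <- seq_len(nrow(obs))
  obs$obs_id <- sprintf("obs%03d", obs$acq_order)
  obs <- obs[, c("obs_id", "group", "time", "batch", "acq_order", "replicate")]

  # deterministic signal ----------------------------------------------
  s_of <- function(tt) if (length(spec$times) == 1) 0.5 else
    (tt - min(spec$times)) / diff(range(spec$times))
  g_index <- function(g) if (g == control) 0L else match(g, exp_groups)
  grand <- vapply(seq_len(p), function(j) {
    v <- outer(spec$times, groups, Vectorize(function(tt, g)
      template_value(template_id[j], g_index(g), s_of(tt), spec$amplitude)))
    mean(v)
  }, numeric(1))

  batch_start <- tapply(obs$acq_order, obs$batch, min)
  X <- matrix(NA_real_, nrow(obs), p)
  for (i in seq_len(nrow(obs))) {
    b <- as.integer(sub("^b", "", obs$batch[i]))
    rel <- obs$acq_order[i] - batch_start[[obs$batch[i]]]
    signal <- if (obs$group[i] == "QC") grand
    else vapply(seq_len(p), function(j)
      template_value(template_id[j], g_index(obs$group[i]),
                     s_of(obs$time[i]), spec$amplitude), numeric(1))
    det <- spec$baseline + signal + offsets[b, ] + spec$drift[b] * rel
    X[i, ] <- if (spec$noise == "additive")
      det + stats::rnorm(p, 0, spec$noise_sd)
    else det * exp(stats::rnorm(p, 0, spec$noise_sd))
  }

  # knowledge base and true annotations -------------------------------
  adducts <- default_adducts()
  n_cmp <- max(4L, min(p, 24L))
  compounds <- data.frame(
    compound_id = sprintf("CPD-%03d", seq_len(n_cmp)),
    name = sprintf("compound_%03d", seq_len(n_cmp)),
    monoisotopic_mass = seq(120, 620, length.out = n_cmp))
  n_ann <- round(spec$annotated_fraction * p)
  pos_adducts <- which(adducts$charge > 0)
  true_ann <- if (n_ann > 0) data.frame(
    peak_id = sprintf("peak%04d", seq_len(n_ann)),
    compound_id = compounds$compound_id[(seq_len(n_ann) - 1L) %% n_cmp + 1L],
    adduct = adducts$name[pos_adducts[(seq_len(n_ann) - 1L) %% length(pos_adducts) + 1L]])
  else data.frame(peak_id = character(0), compound_id = character(0),
                  adduct = character(0))

  mz <- numeric(p)
  for (j in seq_len(p)) {
    if (j <= n_ann) {
      ai <- match(true_ann$adduct[j], adducts$name)
      ci <- match(true_ann$compound_id[j], compounds$compound_id)
      mz[j] <- expected_mz(compounds$monoisotopic_mass[ci], adducts[ai, ])
    } else {
      # off-grid mass, far (Da-scale) from any expected adduct m/z
      mz[j] <- 700 + 0.37 * j
    }
  }
  if (p > n_ann) {
    # keep decoy peaks at least 0.05 Da from every expected adduct m/z
    grid_mz <- as.vector(outer(compounds$monoisotopic_mass, seq_len(nrow(adducts)),
      function(m, a) (adducts$n[a] * m + adducts$mass_shift[a]) / abs(adducts$charge[a])))
    for (j in (n_ann + 1):p)
      while (any(abs(mz[j] - grid_mz) < 0.05)) mz[j] <- mz[j] + 0.11
  }
  peaks <- data.frame(peak_id = sprintf("peak%04d", seq_len(p)),
                      mz = mz, rt = seq(60, 600, length.out = p), mode = "+")

  # pathways: compounds grouped by the template of their first peak
  pw <- if (n_ann > 0) {
    first_peak <- match(compounds$compound_id, true_ann$compound_id)
    used <- !is.na(first_peak)
    data.frame(pathway_id = sprintf("PWY-%d", template_id[first_peak[used]]),
               compound_id = compounds$compound_id[used])
  } else data.frame(pathway_id = character(0), compound_id = character(0))
  pw$name <- if (nrow(pw)) paste0("pathway_", sub("PWY-", "", pw$pathway_id)) else character(0)

  ds <- mtb_dataset(X, obs, peaks)
  kb <- mtb_knowledge_base(compounds, adducts, pw)
  truth <- list(template_id = stats::setNames(template_id, peaks$peak_id),
                batch_offsets = offsets, drift = spec$drift,
                annotations = true_ann, control = control,
                spec = spec)
  list(dataset = ds, kb = kb, truth = truth)
}

#' The eight common electrospray adducts
#'
#' Mass shifts in Da, electron-corrected: [M+H]+, [M+Na]+, [M+K]+,
#' [M+NH4]+, [2M+H]+, [M-H]-, [M+Cl]-, [2M-H]-.
#'
#' @return Data frame with columns `name`, `n`, `charge`, `mass_shift`.
#' @export
default_adducts <- function() {
  data.frame(
    name = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M+NH4]+", "[2M+H]+",
             "[M-H]-", "[M+Cl]-", "[2M-H]-"),
    n = c(1L, 1L, 1L, 1L, 2L, 1L, 1L, 2L),
    charge = c(1L, 1L, 1L, 1L, 1L, -1L, -1L, -1L),
    mass_shift = c(1.007276, 22.989218, 38.963158, 18.033823, 1.007276,
                   -1.007276, 34.969402, -1.007276))
}

#' Write a simulation to the five CSV inputs plus ground truth
#'
#' Writes `intensity.csv`, `observations.csv`, `peaks.csv`,
#' `compounds.csv`, `adducts.csv`, `pathways.csv` and
#' `ground_truth.json` under `dir`, ready for [load_dataset()] /
#' [load_knowledge_base()] or a pipeline config.
#'
#' @param sim result of [simulate_timecourse()].
#' @param dir output directory.
#' @return Invisibly, the written paths.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- write_dataset(sim$dataset, dir)
  p2 <- write_knowledge_base(sim$kb, dir)
  gt <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(template_id = as.list(sim$truth$template_id),
         batch_offsets = sim$truth$batch_offsets,
         drift = sim$truth$drift,
         annotations = sim$truth$annotations,
         control = sim$truth$control),
    gt, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, ground_truth = gt))
}
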