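test_that("expected m/z follows (n*M + shift) / |z|", {
  identity_adduct <- data.frame(name = "[M]+", n = 1L, charge = 1L,
                                mass_shift = 0)
  expect_equal(expected_mz(100, identity_adduct), 100)
  mh <- data.frame(name = "[M+H]+", n = 1L, charge = 1L,
                   mass_shift = 1.007276)
  expect_equal(expected_mz(180.063388, mh), 181.070664, tolerance = 1e-6)
  m2h <- data.frame(name = "[M+2H]2+", n = 1L, charge = 2L,
                    mass_shift = 2 * 1.007276)
  expect_equal(expected_mz(100, m2h), 51.007276, tolerance = 1e-9)
  dimer <- data.frame(name = "[2M+H]+", n = 2L, charge = 1L,
                      mass_shift = 1.007276)
  expect_equal(expected_mz(100, dimer), 201.007276, tolerance = 1e-9)
  expect_error(expected_mz(100, data.frame(n = 1, charge = 0, mass_shift = 0)),
               "charge")
  expect_error(expected_mz(-1, mh), "> 0")
})

test_that("ppm matching annotates within tolerance and not beyond", {
  kb <- make_tiny_kb()          # glucose-like mass, [M+H]+ / [M-H]-
  peaks <- data.frame(peak_id = c("hit", "miss"),
                      mz = c(181.070700, 181.0750),
                      rt = c(1, 2), mode = "+")
  ann <- annotate_peaks(peaks, kb, tol_ppm = 5)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$peak_id, "hit")
  expect_equal(ann$error_ppm, 0.20, tolerance = 0.02)
  expect_identical(ann$confidence, "putative (MSI level 5)")
  # the 23.9 ppm peak only matches at a looser tolerance
  ann30 <- annotate_peaks(peaks, kb, tol_ppm = 30)
  expect_equal(sort(ann30$peak_id), c("hit", "miss"))
  # polarity gate: a negative-mode peak cannot match a positive adduct
  peaks_neg <- transform(peaks, mode = "-")
  ann_neg <- annotate_peaks(peaks_neg, kb, tol_ppm = 5)
  expect_equal(nrow(ann_neg), 0)
  # empty compound table -> no annotations
  kb0 <- mtb_knowledge_base(
    data.frame(compound_id = character(0), name = character(0),
               monoisotopic_mass = numeric(0)),
    default_adducts(),
    data.frame(pathway_id = character(0), compound_id = character(0)))
  expect_equal(nrow(annotate_peaks(peaks, kb0, 5)), 0)
})

test_that("annotation is a set operation, independent of peak order", {
  sim <- simulate_timecourse(simulation_spec(n_peaks = 30, seed = 14))
  pk <- sim$dataset$peaks
  a1 <- annotate_peaks(pk, sim$kb, 5)
  a2 <- annotate_peaks(pk[rev(seq_len(nrow(pk))), ], sim$kb, 5)
  key <- function(a) sort(paste(a$peak_id, a$compound_id, a$adduct))
  expect_identical(key(a1), key(a2))
})

test_that("peaks at true adduct m/z are fully recovered; 2x-tolerance shifts never", {
  sim <- simulate_timecourse(simulation_spec(n_peaks = 40, seed = 9,
                                             annotated_fraction = 0.5))
  truth <- sim$truth$annotations
  ann <- annotate_peaks(sim$dataset$peaks, sim$kb, tol_ppm = 5)
  hit <- paste(ann$peak_id, ann$compound_id, ann$adduct)
  want <- paste(truth$peak_id, truth$compound_id, truth$adduct)
  expect_true(all(want %in% hit))                      # 100% recovery
  # shift every peak by 2x the tolerance: nothing may match
  pk <- sim$dataset$peaks
  pk$mz <- pk$mz * (1 + 10e-6)
  expect_equal(nrow(annotate_peaks(pk, sim$kb, tol_ppm = 5)), 0)
})

test_that("cluster-pathway overlap counts peaks and distinct compounds", {
  # cluster with peaks p1 -> A, p2 -> A, p3 -> B, p4 unannotated;
  # P1 = {A, C}, P2 = {B}
  kb <- mtb_knowledge_base(
    data.frame(compound_id = c("A", "B", "C"),
               name = c("cmpA", "cmpB", "cmpC"),
               monoisotopic_mass = c(100, 200, 300)),
    data.frame(name = "[M+H]+", n = 1L, charge = 1L, mass_shift = 1.007276),
    data.frame(pathway_id = c("P1", "P1", "P2"),
               compound_id = c("A", "C", "B")))
  peaks <- data.frame(peak_id = paste0("p", 1:4),
                      mz = c(101.007276, 101.007276, 201.007276, 555),
                      rt = 1:4, mode = "+")
  ann <- annotate_peaks(peaks, kb, 5)
  m <- matrix(rnorm(4 * 3), 4, 3, dimnames = list(paste0("p", 1:4), NULL))
  model <- dkmeanspp(m, k = 1)
  ov <- pathway_overlap(model, ann, kb)
  expect_equal(ov$n_peaks, c(2, 1))
  expect_equal(ov$n_compounds, c(1, 1))
  expect_equal(ov$pathway_id, c("P1", "P2"))
  expect_equal(ov$compounds[1], "cmpA")
  # invariants: n_compounds bounded by pathway size and annotated peaks
  expect_true(all(ov$n_compounds <= table(kb$pathways$pathway_id)[ov$pathway_id]))
  expect_true(all(ov$n_compounds <= pmax(ov$n_peaks, 1)))

  # no annotations -> all counts zero
  ov0 <- pathway_overlap(model, ann[0, ], kb)
  expect_true(all(ov0$n_peaks == 0) && all(ov0$n_compounds == 0))

  # export: one file per nonzero pair, one compound id per line
  d <- withr::local_tempdir()
  paths <- export_pathway_lists(ov, kb, d)
  expect_length(paths, 2)
  expect_identical(readLines(grep("P1", paths, value = TRUE)), "A")
  expect_length(export_pathway_lists(ov0, kb, d), 0)
})

test_that("two clusters sharing a pathway export distinct files", {
  kb <- make_tiny_kb(masses = c(180.063388, 342.116212),
                     pathways = data.frame(pathway_id = c("P1", "P1"),
                                           compound_id = c("C1", "C2")))
  peaks <- data.frame(peak_id = c("a", "b"),
                      mz = expected_mz(c(180.063388, 342.116212),
                                       data.frame(n = 1L, charge = 1L,
                                                  mass_shift = 1.007276)),
                      rt = 1:2, mode = "+")
  ann <- annotate_peaks(peaks, kb, 5)
  m <- matrix(c(0, 0, 0, 9, 9, 9), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  model <- dkmeanspp(m, k = 2)
  ov <- pathway_overlap(model, ann, kb)
  d <- withr::local_tempdir()
  paths <- export_pathway_lists(ov, kb, d)
  expect_length(unique(paths), 2)
})
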