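---
title: "Methods: batch correction, trend clustering and annotation in metabotrend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: batch correction, trend clustering and annotation in metabotrend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`metabotrend` analyses untargeted LC-MS peak-intensity time courses:
observations (injections) in rows, peaks in columns, with observation
metadata (group, time, batch, acquisition order, replicate; the group
label `"QC"` is reserved for pooled quality-control injections) and
peak metadata (m/z, retention time, polarity). This vignette explains
the models and procedures behind each stage, the parameters that
matter, the numerical conventions, and what the synthetic-data tests do
and do not demonstrate.

## Batch correction

The corrected intensity of peak $p$ in batch $b$, injection $i$, is

$$X'_{p,b,i} = X_{p,b,i} - C_{p,b,i} + R_p
\quad\text{(additive, default)}\qquad
X'_{p,b,i} = X_{p,b,i}\,\frac{R_p}{C_{p,b,i}}
\quad\text{(multiplicative)}$$

where $C$ estimates the technical level of the peak at that injection
and $R$ returns the peak to a working scale. The additive form is the
default because LC-MS batch offsets on a fixed instrument gain are well
approximated as level shifts; the multiplicative form suits data whose
noise scales with intensity (pair it with the simulator's log-normal
noise option when testing that path).

Four estimators of $C$ are provided:

* `qc_mean` — the mean of the batch's QC intensities; constant per
  (peak, batch). Removes level offsets only.
* `qc_linear` — the least-squares line of QC intensity on acquisition
  order within the batch, evaluated at every observation's acquisition
  order. Removes offsets plus linear drift. Needs ≥ 2 QCs per batch.
* `qc_moving_median` — a centered moving median (window in
  acquisition-order units) of the batch's QCs; removes smooth nonlinear
  drift. An observation with no QC in its window takes the nearest QC's
  value rather than extrapolating.
* `background` — a moving median over acquisition order of the batch's
  *non-QC* observations (window default: 10% of the batch's
  acquisition span). This is the option for designs where the pooled QC
  does not track the drift seen in the samples; its trend estimator is
  this package's own definition. Because the trend is sample-driven it
  will also absorb genuine time structure if the run order is
  confounded with time, so randomized injection order is assumed.

$R$ defaults to the per-peak median of **all** QC intensities for the
QC methods and to the per-peak mean of all non-QC intensities for
`background`. A per-peak value constant across batches is essential:
subtracting a per-batch $C$ and re-adding a per-batch level would
restore each batch's offset and make the correction a no-op. The
`batch_mean` rescale option does exactly that recentring and is kept
only for workflows that want within-batch detrending while preserving
batch levels.

Correction quality is scored per peak before/after by: replicate RSD
(percent, `100·sd/|mean|` within each (group, time) replicate cell,
averaged over cells with ≥ 2 replicates); the one-way ANOVA F ratio
across experimental groups (a good correction removes technical
variance, so F should not fall); and the mean pairwise univariate
Gaussian Bhattacharyya distance between batches,

$$D_B = \tfrac14\ln\!\Big(\tfrac14\big(\tfrac{\sigma_1^2}{\sigma_2^2}
 + \tfrac{\sigma_2^2}{\sigma_1^2} + 2\big)\Big)
 + \tfrac14\,\frac{(\mu_1-\mu_2)^2}{\sigma_1^2+\sigma_2^2},$$

zero iff the per-batch distributions coincide. Missing intensities are
never silently zeroed: import flags them, and correction refuses to run
until `impute_missing()` (per (peak, group, time) median, falling back
to the per-peak median) or the user resolves them.

Scaling (`auto`, `pareto`, `range`, `vast`) may run before or after
correction — both orderings are legitimate and deterministic, so the
pipeline config makes the order explicit rather than hard-coding one.
Zero-spread peaks are removed with a warning instead of producing
non-finite values; the significance filter would discard such flat
peaks anyway.

## Trend generation, control correction, input vectors

Replicates at each time point are collapsed by mean or median, then
smoothed by a centered moving mean/median. Window semantics: the
`window` argument is the **total width in the data's own time units**
(days in the simulated design), the interval is closed
(`|t − t₀| ≤ window/2`), and it is truncated at the series edges —
no data are fabricated beyond the observed range. A median over an
even-sized neighborhood is the mean of the two central values. The
default profile smoother is a moving median of width 5, a robust
choice for daily sampling that flattens single-day outliers without
erasing week-scale structure.

Control correction subtracts the control group's smoothed trend from
every experimental observation (at replicate level, not from collapsed
group trends) at its nearest control time point; a gap larger than
`time_tol` (default: the smoothing window) is an error rather than an
extrapolation. Control and QC rows are dropped from the result. The
control-trend smoother is configured independently of the
profile-generation smoother, since the two serve different purposes
(noise suppression vs. trend shape).

Clustering operates on *input vectors*: one smoothed profile per
(peak, group), concatenated across groups in a declared order
(`concatenated`, the default — one vector per peak) or kept separate
(`per_group` — one vector per peak and group, requiring a shared time
grid). Concatenation tolerates groups with different time grids (e.g.
a treatment started a day late); each group block simply contributes
its own length.

## Significance filter

For each peak and experimental group, all time points and replicates
are pooled and compared with the pooled control by a two-sided Welch
t-test (the unequal-variance form, since group variances routinely
differ after stress treatments); the peak's score is
$p_{\min}$, the smallest p value over groups, and the peak is retained
iff $p_{\min} \le \alpha$. Two degenerate cases are resolved
deterministically: two constant pools with equal means give $p = 1$,
with unequal means $p = 0$. No multiple-testing correction is applied
and no inferential meaning is attached — the test is purely a
flatness screen protecting the scaled data from noise-dominated
profiles.

`optimize_alpha()` tunes the threshold against manual labels
(`clear_trend` / `no_clear_trend` / `undecided`) by exhaustive search
on the grid 0.001–0.500 in steps of 0.001, maximizing the fraction of
non-undecided labels reproduced; ties go to the smallest α. Under the
null (all groups distributed as the control) with $G$ effectively
independent group tests, the retained fraction is
$1-(1-\alpha)^G$; the package's calibration check uses a control pool
(150 observations) much larger than each group (15) precisely so that
the shared-control dependence between the $G$ tests is negligible and
the closed form applies.

## d-k-means++ clustering

The deterministic k-means++ variant replaces both sources of
randomness in k-means++ seeding:

1. the seed is an extremal vector — farthest from the grand mean
   (default) or with maximal |Pearson r| against the time axis
   (constant vectors score 0);
2. each further center is the vector maximizing the squared distance
   to its nearest existing center (a parsimony rule instead of the
   probabilistic sampler), until `k` centers exist or, when a coverage
   radius `D_stop` is given, until every vector lies within `D_stop`
   of a center — so `k` need not be fixed in advance;
3. Lloyd refinement alternates nearest-center assignment and
   component-wise mean (k-means) or median (k-medians) updates until
   the assignment is stable, the largest center shift drops below
   `tol = 1e-9`, or `max_iter = 100`.

Distances are Euclidean on the already-scaled input vectors. **Every
tie breaks to the lowest index** — seed choice, farthest vector, and
nearest-center assignment — which is what makes the procedure exactly
reproducible across runs and platforms. Clusters emptied during Lloyd
keep their center frozen and are flagged, rather than being re-seeded,
again to preserve determinism. Because the seed rule is deliberately
extremal, gross outliers can capture it; `drop_outlier_vectors()`
(z-score on distance to the grand mean, default off) or the median
update are the remedies.

Diagnostics: `D` is the arithmetic mean of the per-vector distances to
their assigned centers (averaged over vectors, matching a per-peak
reading); `D_closest10 = dispersion(model, 0.1)` averages the closest
`ceiling(0.1·n)` vectors; the silhouette width is the standard
$(b-a)/\max(a,b)$ with the 0-by-convention for singletons (computed
through `cluster::silhouette`, with an independent brute-force oracle
in the tests); and the BIC is the spherical-Gaussian (x-means style)
score

$$\mathrm{BIC} = \log L - \tfrac{q}{2}\log n,\qquad
q = k\,d + 1,$$

with the pooled maximum-likelihood variance over all vector-to-center
residuals, floored at $10^{-12}$ (a fit at the floor, e.g. $k = n$, is
flagged degenerate). This particular BIC form is this package's
documented choice among the several in circulation; it is comparable
across $k$ on the same vectors, not across datasets. `sweep_k()`
tabulates silhouette/BIC/D over a range of $k$; on continuous spectra
of profiles both criteria tend to favor very small $k$, and the final
choice legitimately remains a judgment call informed by them.

`kmeans_baseline()` is the stochastic reference: best (lowest WCSS) of
N standard Lloyd k-means runs from uniform-random draws of k distinct
vectors, fully reproducible from its RNG seed, with the package's
tie-break rule re-applied to the final assignment.

## Annotation and pathway overlap

A peak matches a (compound, adduct) pair when the adduct's polarity
(sign of its charge) equals the peak's mode and

$$\Big|\,10^6\,\frac{m/z_{\text{obs}} - m/z_{\text{exp}}}
{m/z_{\text{exp}}}\Big| \le \text{tol}_{\text{ppm}},\qquad
m/z_{\text{exp}} = \frac{n\,M + \text{shift}}{|z|}.$$

The default tolerance is 5 ppm, typical for high-resolution
accurate-mass instruments; retention time is not used as a secondary
filter. All matches within tolerance are kept — no best-match pruning —
because several peaks (adducts, in-source fragments) legitimately
represent one compound. Accurate-mass-only annotations are inherently
putative and are labelled "putative (MSI level 5)" throughout.

Pathway overlap counts, per (cluster, pathway), the annotated peaks
whose putative compounds belong to the pathway and the distinct member
compounds covered; rows sort by peak count, then compound count, then
pathway ID. No enrichment p value is computed — the counts are a
ranking device, and an enrichment test on putative annotations would
suggest a rigor the identifications cannot support.
`export_pathway_lists()` writes one compound-ID-per-line text file per
nonzero pair for pathway-tool paste-in.

## The synthetic-data generator

`simulation_spec()` defaults describe a four-group daily stress study:
control plus three treatment groups, days 1–13, 3 replicates per
(group, day), two analytical batches (contiguous halves of a
randomized injection sequence), one pooled QC after every 6th sample,
baseline intensity 100, trend-template amplitude 10 and Gaussian noise
SD 0.5 on the intensity scale — values a practitioner would recognize
as a clean, well-replicated LC-MS study. Peaks cycle over up to five
templates (flat/null, linear, quadratic bump, step, and a mixed
up/down template), applied to the experimental groups only; QC
injections carry the grand-mean signal plus the same batch offset,
drift and noise, mimicking a pooled QC mixed from the whole study. A
configurable fraction of peaks (default 50%) sits exactly at the
expected m/z of known compound/adduct pairs; the rest are decoys kept
at least 0.05 Da from every expected value. Compounds are grouped into
pathways by template so cluster–pathway overlap has a known truth.

What the simulator does **not** emulate — and what passing tests
therefore do not establish about real data: peak-shape and integration
artefacts, missingness mechanisms that correlate with intensity,
nonlinear saturation, correlated noise across co-eluting peaks,
retention-time drift, and real compound-class mass distributions. The
tests demonstrate correctness of the algorithms under their stated
models, not instrument-level robustness.

## Numerical conventions and problem sizes

* Ties: always to the lowest index (seeding, farthest point,
  assignment); `optimize_alpha` ties to the smallest α.
* Degenerate inputs: constant-vs-constant t-test pools resolve to
  p ∈ {0, 1}; constant vectors have time-correlation 0; zero-spread
  peaks are dropped before scaling; the BIC variance floor is
  $10^{-12}$; empty Lloyd clusters freeze.
* Lloyd: `tol = 1e-9` on the maximum center shift, `max_iter = 100`;
  the WCSS trace is recorded and is non-increasing for mean updates.
* The test and acceptance runs use simulated designs of 40–500 peaks,
  ~180 observations, 2 batches and 2000 null peaks for the filter
  calibration — sizes chosen so every property (oracle equivalence,
  exact template recovery, calibration within Monte-Carlo error) is
  sharply testable on a desktop.

## Pipeline and reproducibility

`run_pipeline()` executes the stages in fixed order from one YAML
config, writing per-stage CSV/JSON artifacts, plots and a manifest
(config with defaults filled, package version, per-stage fingerprints
and dimensions). Stage fingerprints chain: each is an md5 over the
stage's configuration plus the upstream fingerprint (for import, the
input files' checksums). On rerun, stages with unchanged fingerprints
keep their files untouched byte for byte; computation is repeated in
memory (it is deterministic and cheap at these sizes) so downstream
stages always receive exact inputs. The filter's p values are computed
on the corrected/scaled data *before* control correction, where the
control group still exists to be compared against.

## Known limitations

* The background-correction trend estimator and the BIC formulation
  are this package's documented choices; other reasonable definitions
  exist and would shift absolute (not comparative) values.
* The Welch filter pools all time points, so a brief, strong deviation
  can be diluted by many baseline-like time points — consistent with
  needing a slightly higher α than conventional testing habits would
  suggest.
* `per_group` input vectors require a shared time grid across groups;
  ragged designs must use concatenated mode.
* Annotation is accurate-mass only (MSI level 5); pathway counts
  inherit that uncertainty and are a prioritization tool, not evidence
  of pathway activity.
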