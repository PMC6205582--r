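Package: metabotrend
Title: Time-Course Trend Analysis for LC-MS Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scriptable workflow for multi-batch LC-MS metabolomic time
    courses: QC-based and background batch correction with quantitative
    quality metrics, peak scaling (auto, pareto, range, vast), moving
    mean/median trend generation and control correction, t-test based
    significance filtering with alpha optimization against manual trend
    labels, deterministic farthest-point k-means++ clustering
    (d-k-means++) with silhouette/BIC model selection and dispersion
    metrics, accurate-mass adduct annotation, cluster-pathway overlap
    scoring, and a ground-truthed synthetic data generator so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    cluster,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
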