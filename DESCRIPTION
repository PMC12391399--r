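Package: lfqpipe
Title: Label-Free Proteomics Differential Expression Pipeline with
    Down-Shifted Gaussian Imputation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for label-free quantitative (LFQ) proteomics
    intensity tables of the kind produced by MaxQuant 'proteinGroups'
    searches, developed around a norflurazon-treatment study design in
    Chlamydomonas reinhardtii (isolates x conditions x biological
    replicates). Implements log transformation, per-sample mean centering
    and distribution-width scaling, validity filtering, probabilistic
    minimum (down-shifted Gaussian) imputation of missing-not-at-random
    values, per-protein F-test variance gating with pooled or Welch
    t-tests, volcano classification of up- and down-regulated proteins,
    Venn region analysis across isolates, descriptive GO-term
    summarization, PCA ordination, and spectrophotometric physiology
    calculations (Evans blue mortality, chlorophyll and carotenoid
    quantification in 80 percent acetone with 720 nm turbidity
    correction). A seeded synthetic-data generator with full ground truth
    emulates the study design, including abundance-dependent dropout, so
    every stage is testable without raw mass-spectrometry data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
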