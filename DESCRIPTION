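Package: combatslide
Title: ComBat Harmonization and Attention-MIL Auditing of Whole-Slide
    Patch Embeddings
Version: 0.1.0
Authors@R:
    person("Pkg", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying and removing tissue-source-site (TSS) batch
    effects in deep patch embeddings of whole-slide images. Provides a
    from-scratch ComBat implementation (empirical Bayes location-scale model
    with parametric or non-parametric priors, additive/multiplicative
    correction modes, and reference-batch alignment for external cohorts), a
    synthetic cohort generator matching the ComBat generative model with
    controllable label signal, site-label confounding and localized artifact
    regions, an attention-based multiple-instance-learning (A-MIL) bag
    classifier, a cross-validated evaluation harness (one-vs-rest AUROC,
    paired t-tests, Benjamini-Hochberg FDR, bootstrap intervals, cohort
    summaries), and per-patch correction-magnitude heatmaps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
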