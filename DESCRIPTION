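Package: concordx
Title: Cross-Platform Expression Concordance and Technical Reproducibility
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analytical-validation toolkit for targeted expression panels
    measured on a digital count platform (NanoString nCounter style) and a
    hybridization-intensity platform (Affymetrix GeneChip style). Implements
    lane-level QC and the positive-control / background / housekeeping
    normalization chain for count data, simplified array QC metrics (scale
    factor, 3'/5' ratios, RNA degradation slope), a technical-reproducibility
    battery (distribution outlier flagging, pairwise Pearson correlation,
    intra/inter-assay precision, PCA, hierarchical clustering, per-gene
    two-way ANOVA mean-square diagnostics), and cross-platform fold-change
    concordance classification (two-fold rule and regression residual-band
    rule), together with a dual-platform synthetic data generator with
    planted ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
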