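Package: phosphoDIA
Title: Phosphorylation-Aware DIA Window Design and Phosphosite
    Differential Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for phosphoproteomic data-independent acquisition (DIA)
    experiments: design of isolation-window schemes with edges placed at
    phosphopeptide forbidden zones, staggered-window layouts and
    gas-phase-fractionation plans, computational demultiplexing of
    staggered scans into effective half-windows, rollup of
    localization-filtered precursor reports to phosphosite-level abundance
    tables, and the downstream label-free statistics used for patient
    group differentiation (QC floor, log2 transform, normality gating,
    completeness filtering, downshifted-normal imputation, median
    normalization, Welch volcano classification, Wilcoxon marker
    selection, random-forest feature ranking, multiclass ROC and linear
    discriminant projection). A seeded synthetic-report generator emulates
    the structure of urinary extracellular-vesicle phosphoproteome
    exports so the full pipeline is testable without raw mass
    spectrometry data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    stats,
    utils
Suggests:
    MASS,
    cluster,
    pROC,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
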