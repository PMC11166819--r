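Package: mplung
Title: Matrix-Pencil Spectral Mapping of Ventilation and Perfusion from
    Free-Breathing Lung MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-wise matrix-pencil spectral decomposition of free-breathing
    dynamic lung MRI series into fractional-ventilation and relative-perfusion
    maps, with quantification of ventilation and perfusion defect percentages,
    matched ventilation/perfusion defects and a defect distribution index,
    both whole-lung and per lung side. Includes translation-based motion
    compensation, a fallback intensity-based lung segmentation, a synthetic
    dynamic phantom generator with plantable defects for end-to-end testing,
    and the cohort statistics stage: one-way ANOVA with Tukey-Kramer,
    Games-Howell and Benjamini-Hochberg post hoc procedures (from raw values
    or printed group summaries), mixed repeated-measures ANOVA for
    group-by-lung-side interactions with Bonferroni-adjusted paired contrasts,
    and Spearman correlation screens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    EBImage,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
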