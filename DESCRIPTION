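Package: mrplanqa
Title: Plan Quality and Tissue-Air Interface Dosimetry for MR-Guided
    Head-and-Neck Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Dosimetric evaluation of head-and-neck IMRT plans on a 1.5-T
    MR-linac, where the electron return effect perturbs dose at tissue-air
    interfaces. Provides anisotropic Euclidean distance transforms for
    deriving bespoke regions (1-mm skin shell, 1-mm air-cavity interface
    shells, planning organ-at-risk margins, normal tissue), cumulative
    dose-volume histograms and the standard plan metrics (Vp, Dq%, Dmax,
    Dmean, homogeneity and conformity indices), a 15-submetric piecewise
    linear plan-quality metric (PQM) score, paired three-condition plan
    comparison with SPSS-style asymptotic Wilcoxon signed-rank tests and
    voxel-wise dose-difference maps, and a synthetic neck-phantom dose
    generator that emulates magnetic-field skin boost and antisymmetric
    cavity-interface shifts so the full analysis runs without patient data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
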