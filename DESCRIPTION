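Package: glycomig
Title: IgG Fc N-Glycopeptide MALDI-TOF Profiling and Migraine Classification
Version: 0.1.0
Authors@R:
    person("Glycomig", "Developers", email = "glycomig@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for serum immunoglobulin G (IgG) Fc
    N-glycopeptide profiling by linear-mode MALDI-TOF mass spectrometry:
    a theoretical glycopeptide mass library over the IgG1/IgG2/IgG3-4
    subclass backbones, top-hat (morphological opening) baseline
    subtraction, threshold peak picking with internal affine mass
    calibration, compositional relative quantification with technical
    replicate averaging and RSD repeatability QC, derived glycan traits
    (bisecting GlcNAc, fucosylation, sialylation, galactosylation ratio),
    two-group cohort statistics, and a small feedforward neural-network
    case/control classifier evaluated by stratified 5-fold
    cross-validation. A synthetic-cohort generator produces spectra and
    compositional profiles with known ground truth so that every stage is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
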