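Package: fpcrevise
Title: NMR Fingerprinting, DFT-NMR and ECD Post-Processing for
    Phloroglucinol Structure Revision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for computational structure revision of
    formyl phloroglucinol meroterpenoids. Builds diagnostic 1H/13C chemical
    shift fingerprints and classifies compounds by principal component
    analysis and nearest-centroid assignment, flagging structures whose
    reported substructure class is inconsistent with their shifts. Converts
    DFT-calculated conformer ensembles (relative energies plus isotropic
    shielding tensors) into Boltzmann-averaged, empirically scaled chemical
    shifts, scores candidate structures against experimental assignments by
    MAE/RMSD, and discriminates candidates with DP4+ Student-t probability
    analysis. Synthesizes electronic circular dichroism spectra from
    rotatory-strength transition tables (Gaussian band broadening, Boltzmann
    weighting, UV wavelength correction) and scores agreement with
    experimental traces. Includes seeded synthetic-data generators emulating
    the statistical structure of each input so the whole pipeline is testable
    without quantum-chemistry runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
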