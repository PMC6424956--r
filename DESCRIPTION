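Package: isopair
Title: Isotope-Pair MALDI-TOF Quantification of Peptide Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of peptide transport across in vitro barrier
    models (transwell and PAMPA) using light/heavy acetyl isotope pairs
    measured by MALDI-TOF mass spectrometry. Provides elemental
    compositions, monoisotopic masses and isotopologue envelopes for
    peptides with isotopically labeled acetyl termini; a seeded synthetic
    MALDI-TOF spectrum generator; peak picking, light/heavy envelope
    matching and area-ratio quantification with optional envelope-overlap
    correction; transport (%) and apparent permeability from transwell
    assays in HPLC-area and MALDI-ratio modes; PAMPA effective
    permeability; and serial-dilution limit-of-quantification analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mzR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
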