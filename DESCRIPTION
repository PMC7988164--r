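Package: glaquant
Title: DIA Mass Spectrometry Quantification of Factor IX
    Gamma-Carboxylation, Site-Specific PTMs and Host Cell Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring the yield and quality of a recombinant
    coagulation factor IX product across a fed-batch bioreactor run using
    data-independent acquisition (DIA/SWATH) mass spectrometry.  Provides a
    monoisotopic mass calculus for peptidoforms (glycans, gamma-carboxylation,
    methyl-ester derivatization, fragment and diagnostic ions), SWATH
    isolation-window schemes with co-isolation conflict detection, ion-library
    construction and TSV round-tripping, transition-level label-free
    quantification with FDR filtering and reference normalization,
    carboxyform stoichiometry and PTM occupancy time courses, two-stage FDR
    screening and a protein-level differential-abundance procedure, and a
    synthetic fed-batch data generator so that every stage runs and can be
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
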