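Package: fucoscreen
Title: Fluorescence-Based Screening and Flux Correlation Analysis for
    Carotenoid-Hyperproducing Diatom Mutants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for high-throughput screening of chemically mutagenized
    diatom libraries for elevated carotenoid (fucoxanthin) content.
    Implements spectrophotometric pigment quantification from methanol
    extracts, fluorescence-threshold screening of plate-reader wells
    (chlorophyll-a and Nile red channels), a three-stage mutant selection
    pipeline with long-term stability assessment, growth-rate and
    mutagen-lethality metrics with diphenylamine dose-response summaries,
    uniform sampling of steady-state flux polytopes of small stoichiometric
    models with correlation analysis against a fucoxanthin-production
    reaction, and a calibrated synthetic plate-reader data generator so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    MASS,
    stats,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
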