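Package: ivmscreen
Title: Automated Genotoxicity Assessment from High-Content In Vitro
    Micronucleus Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a rule-based statistical workflow for automated
    genotoxicity assessment from high-content in vitro micronucleus (IVM)
    screening data: per-plate CC50 exemplar selection with flanked-label
    smoothing and precipitation well-masking, micronucleus fold-change
    genotoxicity flagging, plate-control-anchored Gaussian mechanism
    (aneugen/clastogen) scoring, and cell-cycle deconvolution of single-cell
    Hoechst intensities via a Dean-Jett-Fox adaptation fitted by Nelder-Mead.
    A synthetic screen generator emulates 384-well plate structure, control
    wells, dose-dependent cytotoxicity and precipitation artifacts so the
    whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
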