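Package: sensilphys
Title: Sensillum Support-Cell Physiology: Cation Imaging and Single-Sensillum
    Recording Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for Drosophila antennal sensillum physiology.
    Transforms ROI-averaged fluorescence matrices from live cation (Ca2+/K+)
    imaging into background-subtracted dF/F0 time courses, classifies
    responding cells, aggregates replicates with standard errors, and extracts
    dose-response curves at the population extremum timepoint. Analyses
    single-sensillum recording (SSR) spike trains: stimulus response
    magnitudes, resting-activity estimation by two cross-checked estimators,
    peristimulus frequency traces in 25 ms bins, and a three-step air-gust
    (mechanoresponse) correction with rolling-average smoothing and
    peak/area-under-curve quantification. A synthetic-data module simulates
    fluorescence recordings and inhomogeneous-Poisson spike trains with known
    ground truth so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    zoo,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
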