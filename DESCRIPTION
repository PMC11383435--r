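Package: knockoutDepletion
Title: Knockout-Depletion Analysis of Essential-Protein Overabundance
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing knockout-depletion experiments in naturally
    competent bacteria, in which an essential gene is deleted and the
    pre-existing protein pool is diluted by growth until function fails.
    Implements single-cell lineage analysis (dilution model, areal growth
    rates, arrest detection, fitness landscapes), classification of
    transposon-library (TFNseq) relative-abundance trajectories into
    no-effect, sufficient and overabundant classes via nested breakpoint
    models and sequential F-tests, conversion of arrest times to protein
    overabundance, message-number computation from RNA-seq counts, the
    Robustness-Load Trade-Off (RLTO) optimality model predicting
    overabundance from transcription level, and genome-scale summary
    statistics. A seeded synthetic-data generator reproduces the statistical
    structure of the imaging, sequencing and RNA-seq inputs so the entire
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Software, Sequencing, SingleCell, CellBiology, GeneExpression
RoxygenNote: 7.3.3
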