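Package: nichejump
Title: Collective cAMP Signalling and the Developmental Transcriptome Jump
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of how collective cAMP oscillations drive a
    rapid, concerted transition (the "jump") between cell states in the
    Dictyostelium developmental niche. Provides a seeded synthetic-data
    generator emulating the study system (an oscillatory cAMP field with a
    moving onset boundary, lag-coupled nascent-transcription reporters under
    one-step and two-step gene models, optogenetic pulse trains, feeding-front
    colony time-lapses with discrete mound-formation events, and paired
    wild-type/acaA-null negative-binomial single-cell count matrices over a
    gapped pseudotime); image quantification (transcription-spot detection,
    biosensor masking, kymographs); signalling/transcription coupling
    statistics (inflection boundaries, periods, cross-correlation lags,
    induction onsets, frequency-response classification); colony dynamics
    (front-speed and inter-mound interval statistics); and single-cell
    transcriptome analysis (normalisation, PCA, density-gap jump detection,
    correlation clustering, gene categorisation, and cAMP-dependence
    classification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    EBImage,
    cluster,
    jsonlite,
    methods,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
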