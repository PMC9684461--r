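Package: kisflux
Title: Steady-State mRNA Synthesis-Decay Kinetics and Import-Sensitive
    Decay Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative analysis of mRNA buffering in
    budding yeast: inference of per-gene transcription rates (TR), mRNA
    abundances (RA) and steady-state half-lives (HL = RA/TR) from genomic
    run-on (GRO) style measurements; scoring and classification of
    import-sensitive (Kis) mRNAs from mutant/wild-type fold-changes;
    equal-size Kis-value binning with per-bin median summaries; poly(A)
    read selection and polyadenylation-site window counting for RIP-seq
    style data; transcription-shutoff decay-curve fitting; spike-in count
    normalization; closed-form single-gene mRNA response dynamics; and a
    seeded synthetic-data generator implementing a two-pathway decay model
    with synthesis-decay buffering, so that every stage of the pipeline is
    testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
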