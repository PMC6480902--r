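Package: ovage
Title: Aging Expression Analysis for Drosophila Stage-14 Egg Chambers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for transcriptome aging studies in Drosophila
    late-stage egg chambers across inbred strains. Implements RPKM summaries
    and log2 old/young aging ratios, negative-binomial differential expression
    for age, strain and strain-by-age effects with BH false discovery control,
    an expression-matched permutation test for coordinated gene-set shifts
    (e.g. the piRNA machinery), directional sign tests for chorion and
    mitochondrial sets, positional enrichment of differentially expressed
    genes in heterochromatin domains and on the dot chromosome using
    Yates-corrected chi-squared tests, transposable-element family aging
    statistics, correlation-based oogenic stage verification, and a
    negative-binomial synthetic-data generator that emulates the two-strain
    two-age study design for calibration and recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    MASS,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    fgsea,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
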