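Package: chipcalib
Title: Quantitative ChIP-Seq Calibration and Twofold Expression Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a globally calibrated ChIP-seq normalization chain for
    histone-modification tracks (binned read coverage, unit-mean scaling,
    Poisson-model input subtraction, Western-blot global calibration) together
    with gene-body and strand-aware TSS metagene summaries and the
    H3K36me2/H3K27me3 ratio statistic. A companion expression module computes
    RPKM, calls twofold up/down regulation with a pseudocount, partitions
    induced genes into mutant-sensitive and mutant-resistant sets, intersects
    partitions, and ranks depot-selective genes by log2 fold change. A
    synthetic-data generator plants known global depletion factors, enrichment
    domains and induced/sensitive gene sets so the whole pipeline is testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    GenomeInfoDb,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
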