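Package: fruitMethyl
Title: Whole-Genome Bisulfite Methylome Analysis Across Fruit Development Stages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for whole-genome bisulfite sequencing (WGBS)
    methylomes sampled across fruit developmental stages. Implements
    bisulfite conversion-rate estimation from an unmethylated spike-in,
    binomial methylcytosine calling, weighted methylation levels in the
    CG/CHG/CHH contexts, fixed-window differentially methylated region
    (DMR) calling with Fisher's exact test and Benjamini-Hochberg FDR,
    strand-aware metagene methylation profiles over gene and transposon
    bodies with 2 kb flanks, DMR density near transcription start and end
    sites against a random-placement background, and association of DMRs
    with differentially expressed genes via the hypergeometric test.
    Includes a calibrated synthetic bisulfite-count generator with ground
    truth so the whole pipeline can be exercised and validated at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
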