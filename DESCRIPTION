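Package: clipmap
Title: Cross-Link Peak Calling and Splicing Integration for iCLIP and
    RNA-Seq
Version: 0.1.0
Authors@R:
    person("clipmap", "authors", email = "maintainer@clipmap.dev",
           role = c("aut", "cre"))
Description: Tools to analyse individual-nucleotide resolution UV
    cross-linking and immunoprecipitation (iCLIP) data together with
    knockdown RNA-seq splicing data. Implements randomization-based
    false discovery rate peak calling on cross-link reads within gene
    regions, control subtraction and 2-of-3 replicate consensus with
    re-pooled re-calling, peak annotation and positional metaprofiles
    (exon-junction-complex style canonical-site profiles, intron
    boundary histograms, RNA maps), read-count based CLIP+/CLIP- intron
    classification with median-of-ratios expression filtering, percent
    spliced in (PSI) and percent intron retention (pir) quantification
    with probabilistic differential-event acceptance filters, and
    integration of binding with splicing changes. A synthetic-data
    module plants known binding sites and splicing effects so every
    stage can be exercised and scored against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    withr,
    yaml,
    rtracklayer
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
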