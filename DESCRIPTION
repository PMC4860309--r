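Package: profdiff
Title: Differential Enrichment Analysis of ChIP-Seq Metafeature Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares histone-modification enrichment profiles around classes
    of genomic elements (for example transcription start sites) between
    experimental groups at nucleotide resolution. Uses biological replicates
    and chromatin Input samples: scaled Input counts provide position-specific
    normalization factors for a negative-binomial generalized linear model,
    Wald tests against a minimum log2-fold-change threshold assess each
    position, and local false discovery rates derived from a Grenander
    (monotone) density estimate of the p-values quantify per-position
    significance. Includes fragment-midpoint counting from SAM/BAM alignments
    around GFF-derived anchors, robust trimmed-mean profile summarization,
    plotting of smoothed and significance-annotated profiles, a synthetic-data
    generator with known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    DESeq2
Config/testthat/edition: 3
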