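Package: peakrescue
Title: Consensus Peak Calling and Weak-Peak Rescue Across Replicated
    ChIP-Seq Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processes replicated ChIP-seq peak calls to rescue weak
    but reproducible binding sites. Peaks called at a permissive threshold
    are classified as stringent, weak or background; colocalized peaks
    across replicates are tested jointly with Fisher's combined probability
    test, confirmed or discarded according to the replicate type
    (biological or technical), corrected per sample with the
    Benjamini-Hochberg procedure, and merged into consensus regions scored
    by combined stringency (chi-squared and combined p-value). Also
    provides an annotation-enrichment z-test comparing the per-nucleotide
    probability of annotation inside versus outside a peak set, a
    ground-truth simulator for replicated peak sets, and tidy/ggplot2
    accessors for all result types.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
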