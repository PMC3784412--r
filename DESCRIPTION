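Package: hoodscore
Title: Gene Neighborhood and Chromatin Domain Scoring for Tissue Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrative scoring of gene-neighborhood organization and
    chromatin state between two tissues. Scores every candidate window of
    2-10 adjacent probed genes with a Total Neighborhood Score (TNS)
    combining average pairwise expression correlation, synteny conservation
    across comparison genomes, and a randomized-transcriptome permutation
    p-value. Summarizes broad histone-mark islands (H3K4me2, H3K36me3,
    H3K27me3) into chromatin active/silenced domain ratios and a combined
    domain score per gene and per neighborhood, classifies genes and gene
    pairs by differential chromatin state, profiles co-expression as a
    function of genomic distance, finds detection-call run neighborhoods and
    cross-tissue sharing, and provides a simplified broad-island caller with
    the aggregate-score gap-size scan. A synthetic-data generator with
    planted ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
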