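Package: clustom
Title: OTU Clustering of 16S rRNA Amplicons by k-mer-Calibrated Graph Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters 16S rRNA amplicon reads into operational taxonomic
    units (OTUs) with the CLUSTOM algorithm: a k-mer distance threshold is
    calibrated on a random sample against the Needleman-Wunsch (NW)
    distance so that no sampled pair is a false positive, initial clusters
    are extracted greedily from the k-mer similarity graph by iterative
    maximum-degree seed selection, and seeds plus singletons are refined
    with exact NW alignment at each user threshold. Includes the
    taxonomy-based (per-taxon precision/recall, F-measure) and
    distance-based (false conjunction/disjunction against per-OTU core
    sequences) accuracy metrics, and a synthetic amplicon community
    generator with planted cluster structure for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    knitr,
    mclust,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
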