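Package: tadfam
Title: Classification of Topologically Associating Domains into Structural and Functional Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs three-dimensional bead models of topologically
    associating domains (TADs) from Hi-C contact matrices by converting
    contacts to wish distances and embedding them with metric
    multidimensional scaling, scores pairwise structural similarity with a
    TM-score over rigid superpositions, quantifies chromatin-state fold
    enrichment per TAD, spectrally clusters both similarity matrices, and
    defines TAD families as the intersections of structural and
    chromatin-state clusters, with enrichment scores, averaged contact
    heatmaps, cross-cell-type TAD pairing, and gene/lncRNA annotation
    mapping. Includes a synthetic-data generator with planted structural
    and chromatin-state classes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
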