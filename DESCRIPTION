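Package: dhsatlas
Title: DNase I Hypersensitivity Mapping, Temporal Clustering and
    Cross-Species Conservation of Regulatory Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects DNase I hypersensitive sites (DHSs) from aligned
    cleavage tags with a binomial local-background model, calibrates the
    detection threshold to a target false discovery rate with simulated
    random-read datasets, and computes the SPOT library-quality score.
    Builds a non-redundant cross-sample master list of DHSs, normalizes
    per-stage accessibility (SPOT correction, log10 transform, row
    scaling to a maximum of 10), partitions DHSs into temporal groups by
    k-means, annotates DHSs against genomic features, ChIP-seq occupancy
    and region specificity, tests per-cluster transcription-factor motif
    enrichment by the cumulative hypergeometric distribution with
    Bonferroni correction, and classifies cross-species DHS conservation
    from an orthology interval map. A synthetic-data generator with
    known ground truth exercises the full pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
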