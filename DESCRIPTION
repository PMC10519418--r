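Package: orthosweep
Title: Ortholog Alignment Filtering and Gene-Tree Concordance Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quality control and diagnostics for phylogenomic datasets built
    from per-ortholog coding-sequence clusters. Implements a three-step
    ortholog-alignment filter (length variation, uncorrected pairwise
    distance, missingness) with codon-aware alignment, trimming and
    back-translation; tree comparison and per-branch concordance statistics
    (Robinson-Foulds distance, clade recovery, gene concordance factor,
    quartet support); a quartet-agreement species-tree estimator with an
    exhaustive small-taxon oracle; a locus-subsampling experiment for sizing
    minimal diagnostic marker panels; genomic locus-independence summaries;
    and a multispecies-coalescent simulator with artifact injection so every
    component is testable from synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
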