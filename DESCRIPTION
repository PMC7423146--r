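Package: phyloprof
Title: Phylogenetic Profiling of Gene Families with Weighted MinHash and
    LSH Forest Retrieval
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds event-aware phylogenetic profiles for hierarchical
    orthologous groups (HOGs). Gene families supplied in OrthoXML are
    reconciled against a reference species taxonomy to infer, per taxonomic
    node, presence, loss, duplication and copy number of the family. The
    resulting weighted multiset profiles are sketched as weighted MinHash
    signatures (consistent weighted sampling) whose per-position collision
    probability equals the weighted Jaccard similarity, and indexed in an
    LSH Forest for sub-linear top-k retrieval of co-evolving families.
    Downstream tools build all-vs-all Jaccard kernels, cut UPGMA cluster
    modules at a flat height, compute baseline profile metrics and ROC/AUC
    benchmarks on labelled family pairs, and simulate gene families
    evolving on a species tree under gain, loss and duplication (including
    co-evolving pairs with correlated losses) with exact logged ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
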