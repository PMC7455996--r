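Package: kmertax
Title: K-mer LCA Taxonomic Classification and Abundance Re-Estimation for
    16S rRNA Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale 16S rRNA metataxonomic analysis stack: builds a
    canonical k-mer to lowest-common-ancestor (LCA) database from reference
    sequences carrying Greengenes-style lineage strings, assigns reads to
    taxa by root-to-leaf path scoring over k-mer hits, redistributes reads
    classified above a target rank down to genus or species level in
    proportion to empirically re-classified reference windows, and scores
    the results with abundance-weighted mean absolute proportion error,
    Bray-Curtis dissimilarity, and per-read sensitivity and precision with
    vague-positive accounting. Includes a synthetic 16S community and
    paired-end amplicon read simulator with ground truth so the whole
    pipeline runs with no external databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
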