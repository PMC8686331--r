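Package: mutblot
Title: Context-Aware Clustering of Single-Base Substitutions with a
    Recurrent Feature Extractor and a Repulsive Self-Organizing Map
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters somatic single-base substitutions (SBSs) by their
    mutated base together with long flanking sequence context.  Each
    mutation and its flanks are encoded as a numeric matrix, read from
    both ends toward the mutation site by a two-layer LSTM that emits an
    8-dimensional feature vector, and clustered with a modified
    self-organizing map whose competition units are attracted to or
    repelled from each input under a rank-based distance threshold; the
    inputs themselves receive a feedback update that is re-used as the
    regression label for the extractor.  A recursive binary splitting
    schedule yields "mutation blot" (MB) classes.  Downstream tools
    compute per-patient MB compositions, K-means patient classes with
    elbow selection, flank-composition spectra, group-comparison
    statistics and log-rank survival tests.  A synthetic-data module
    generates toy reference genomes, MAF files with planted context
    signatures and clinical tables so the whole pipeline runs without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
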