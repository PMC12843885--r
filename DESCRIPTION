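Package: fiemspipe
Title: Untargeted FIE-MS Metabolomics Pipeline for Tea-Processing Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and analysis of flow-infusion electrospray ionisation
    mass spectrometry (FIE-MS) fingerprints collected across ordered
    tea-manufacture stages. Provides spectral binning of centroided scans into
    polarity-tagged m/z features with occupancy and pooled-QC filtering,
    moisture/weight normalisation of extracts, adduct-rule molecular formula
    assignment with tiered compound matching and consensus chemical-taxonomy
    classification, random-forest stage regression with permutation-based
    feature selection, k-means trend clustering of percentage relative
    abundance profiles, personalized-PageRank functional enrichment on a
    compound knowledge graph, Fisher's-exact structural enrichment, and
    Welch's t-test differential analysis between process arms. A seeded
    synthetic-data module generates complete datasets with known ground truth
    for validation of every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    jsonlite,
    mzR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph,
    cluster
Config/testthat/edition: 3
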