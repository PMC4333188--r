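Package: coreppi
Title: Predicting Protein-Protein Interactions from Dense Complex Subnetworks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes detected protein complexes into dense subnetworks of a
    protein-protein interaction (PPI) network by seeding k-cliques and greedily
    extending them under a density threshold, then predicts the missing
    within-subnetwork interactions. Repeated predictions across overlapping
    complexes are tracked with a repetition counter and can be filtered for
    confidence. Includes the matching evaluation suite (gold-standard
    likelihood ratio, reference-interactome hit ratio, prediction-set overlap
    statistics, annotation-based complex hit ratio), readers and writers for
    the plain-text edge-list and complex formats, a synthetic planted-complex
    generator for benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    optparse,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
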