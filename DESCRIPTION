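Package: comopath
Title: Comorbid-Disease Pathway Crosstalk and Interactome Candidate Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative pathway and protein-interaction analysis for a pair
    of comorbid diseases. Takes two disease susceptibility gene lists, GMT
    pathway annotations and a protein-protein interaction table, and performs
    two-cluster hypergeometric over-representation with Benjamini-Hochberg
    adjustment and cluster-specificity classification, builds a kappa-score
    pathway crosstalk network with an overlaid gene-pathway bipartite graph,
    and infers pleiotropic candidate proteins and hub proteins by
    guilt-by-association on the interactome. Includes a seeded synthetic-data
    generator with planted ground truth so the full pipeline is testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
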