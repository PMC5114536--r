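Package: transkingdom
Title: Transkingdom Network Analysis and Causal Inference for
    Host-Microbiome Interactions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies cytokine-regulated gut microbes from paired
    perturbation experiments by direction-concordant differential
    abundance, screens them as candidate mediators of a host phenotype by
    sign-matched within-group correlation, reconstructs host gene
    co-expression networks from per-group Pearson statistics merged with
    Fisher's combined probability test, and prioritizes host genes as
    regulators of a target microbe with a four-source rank-sum score.
    Includes a synthetic-data generator that plants known mediators and
    regulators so every stage of the inference chain can be verified
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
biocViews: Microbiome, NetworkInference, GraphAndNetwork,
    DifferentialExpression, Metagenomics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
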