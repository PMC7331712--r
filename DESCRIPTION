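Package: metaphenet
Title: Integrated Metabolic and Co-Expression Network Analysis of
    Multi-Condition Microbiome Omics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying condition-specific gene functions in
    microbial communities by integrating detected metabolites and
    over-expressed genes into a master metabolic reaction network through
    minimal (Steiner) connecting subnetworks, inferring unweighted gene
    co-expression networks from mutual-information Z-scores (context
    likelihood of relatedness, CLR), and analysing the centrality and
    network neighbourhoods of the condition-specific genes. Includes a
    synthetic multi-omics generator with planted co-expression modules and
    condition-responsive pathways so every stage can be validated against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    splines,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
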