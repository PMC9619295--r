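Package: rewireHMRF
Title: Guilt-by-Rewiring Gene Prioritization from Weighted Differential
    Co-Expression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Ranks genes by their posterior probability of association with a
    binary phenotype (e.g. drought stress) from two-condition expression data.
    Candidate genes are screened with a permutation mean-variance (MV)
    independence test, weighted gene differential co-expression networks
    (WGDCNs) are built from grey correlation coefficients, and a hidden Markov
    random field with an Ising prior over the rewiring network is solved by
    iterated conditional modes to obtain per-gene posterior probabilities.
    Includes multilayer-network summaries across developmental stages and a
    synthetic two-condition expression generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    pROC,
    xml2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
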