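Package: refrank
Title: De Novo Discovery of Stable Reference Genes Across Expression Data Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks candidate reference ("housekeeping") genes across two or
    more gene-expression data sets by combining, per data set, the coefficient
    of variation and the condition-vs-control fold change into a joint rank
    product, then aggregating rankings over data sets with a dataset-level
    bootstrap and penalising genes absent from part of the compendium.
    Companion statistics include a NormFinder-style expression-stability
    score, gene-list concordance measures (overlap coefficient,
    reproducibility R, hypergeometric overlap test), comparative 2^-ddCt
    normalization of RT-qPCR data against single reference genes or
    multi-gene panels, and a synthetic-compendium simulator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
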