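Package: cidnet
Title: Directed Gene Regulatory Network Inference with the Coefficient of
    Intrinsic Dependence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers directed gene regulatory networks from normalized
    expression matrices using the coefficient of intrinsic dependence (CID),
    a nonparametric dependence measure based on discrepancies between
    kernel-smoothed conditional and marginal distribution functions, and its
    partial extension (pCID) for stepwise regulation-path elongation.
    Significance is assessed by response-permutation tests.  Includes the
    three-step network construction procedure (seed-pair identification,
    pCID-driven elongation with direction assignment, sub-network assembly)
    in supervised and unsupervised modes, a normal-mixture network simulator
    for validating edge and direction recovery, promoter G-box scanning for
    source/target role assignment, and readers/writers for expression
    matrices and edge-list/SIF/GraphML network formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
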