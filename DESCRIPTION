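Package: SigScan
Title: Gene-Signature Extraction and Conservation Scanning Across
    Expression Compendia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Extracts a driver-stratified differential gene signature from an
    expression matrix, scans collections of expression series for sample pairs
    in which the signature genes change coordinately using an exact binomial
    sign-coordination statistic with Holm correction, mines series annotations
    for enriched terms with Fisher's exact test, computes gene-set enrichment
    ratios and hypergeometric significance against a background universe, and
    summarizes gene co-expression neighborhoods as a biclique-constrained
    cluster graph. A synthetic-data module generates every input with planted
    truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'signature.R'
    'scan.R'
    'annotation.R'
    'enrichment.R'
    'graph.R'
    'simulate.R'
    'io.R'
    'cli.R'
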