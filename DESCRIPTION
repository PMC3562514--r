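Package: mirhostpred
Title: Predict miRNA Differential Expression and Targets from mRNA Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts differential microRNA expression from mRNA-only
    expression matrices by exploiting the co-expression of intragenic
    miRNAs with their protein-coding host genes.  Two predictors build a
    miRNA pseudo-expression matrix: a weighted scaling function over
    mapped host-gene expression and a per-miRNA least-squares linear
    model trained on paired data.  Putative targets are extracted by
    expression anti-correlation, annotated by hypergeometric gene-set
    over-representation, and validated with a sliding-window
    miRNA:3'UTR duplex free-energy scan.  Includes a synthetic-data
    generator with planted host correlations, targets, enriched terms
    and binding sites so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    limma,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    IRanges
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
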