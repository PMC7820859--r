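Package: eabench
Title: Benchmarking Framework for Gene Set Enrichment Analysis Methods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained benchmarking harness for gene set enrichment
    analysis (EA) methods. Re-implements six widely used competitive and
    self-contained methods (ORA, GSEA, SAFE, PADOG, CAMERA, SAMGS) behind a
    single interface, generates synthetic expression datasets, gene set
    collections and phenotype relevance rankings with controlled structure,
    and evaluates methods for statistical significance behaviour, type I
    error under sample-label randomization, gene-set-size dependency, and
    phenotype relevance of their rankings via a rank-weighted relevance
    score normalized by its theoretical optimum. Includes a
    variance-stabilizing log-CPM transformation that makes microarray-era
    permutation methods applicable to RNA-seq counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    edgeR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
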