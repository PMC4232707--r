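Package: sfltest
Title: Short Focus Level Multiple Testing on Gene Ontology Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Familywise error rate controlled gene-set testing on Gene
    Ontology style directed acyclic graphs. Implements the Short Focus
    Level procedure, a sequentially rejective graphical weighted-Bonferroni
    shortcut of the closed-testing Focus Level method for the restricted
    (nested) hypotheses of a gene-set DAG, together with the brute-force
    closed-testing machinery used as a correctness oracle, self-contained
    gene-set tests (Stouffer and Fisher p-value combination, a global score
    test for expression data), simulation generators for count and Gaussian
    expression studies, and readers and writers for OBO, GMT, TSV and DOT.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
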