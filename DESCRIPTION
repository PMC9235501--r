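Package: zeroGO
Title: Ontology-Constrained Protein Function Prediction with EL n-Ball
    Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Joint embedding of Gene Ontology classes as n-balls constrained
    by EL normal-form axiom losses, together with a residual multilayer
    perceptron that projects proteins (binary domain-annotation vectors)
    into the same space. Supports supervised and zero-shot prediction of
    ontology classes, sequence-similarity annotation transfer by normalized
    bitscore, similarity-group dataset splitting, and the CAFA evaluation
    suite (Fmax, Smin, AUPR, class-centric AUC, information-content
    summaries). Includes an OBO parser, EL axiom normalization into the
    four normal forms, true-path-rule annotation propagation, and a
    synthetic fixture generator with a planted, recoverable
    feature-to-function signal.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
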