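Package: glsma
Title: Slime Mould Optimization with Gaussian Mutation and Levy Flight for
    Gene Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements the slime mould algorithm (SMA) and a boosted variant
    (GLSMA) that adds a Gaussian mutation operator for population diversity and
    a Levy-flight escape move for leaving local optima, together with a binary
    wrapper variant (BGLSMA) for feature selection on high-dimensional
    gene-expression data using a 1-nearest-neighbour classifier under
    stratified cross-validation. Ships the 23 classical box-bounded benchmark
    functions used to evaluate continuous metaheuristics, a seeded synthetic
    gene-expression generator with planted informative genes, and an experiment
    harness with Wilcoxon signed-rank and Friedman average-rank comparisons.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
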