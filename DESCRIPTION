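Package: mutatorQS
Title: Quasispecies Dynamics with a Mutator Gene
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solvers and analytic theory for infinite-population quasispecies
    models in which a mutator locus raises the genomic mutation rate and may
    alter the fitness landscape.  Implements the two-chain Crow-Kimura
    (parallel mutation-selection) model on Hamming classes with forward and
    backward switching between wild-type and mutator sub-populations, and the
    corresponding Eigen (coupled mutation-selection) model.  Provides exact
    finite-genome steady states via dominant eigenpairs of the linearised
    system, nonlinear dynamics, large-genome Hamilton-Jacobi potentials and
    mean-fitness formulas, WKB computation of the mutator-allele fraction,
    single-peak closed forms, phase classification and phase diagrams, and
    drivers that recompute the published mean-fitness tables and figure-level
    quantities from scratch.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
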