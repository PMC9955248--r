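Package: bntissue
Title: Coupled Boolean Network Tissues with Multilayer Ising Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models populations of cells as isogenic random Boolean networks
    with gene-expression perturbation noise, coupled on a periodic 2D lattice
    through a multilayer Ising Hamiltonian acting on control-kernel genes.
    Provides exact Markov-chain and Monte Carlo steady-state distributions,
    control-kernel pinning and dynamic (stochastic) pinning, hybrid
    Metropolis/synchronous-update tissue simulation, annealing sweeps,
    mixture-based cell-type detection (constrained least squares, spectral
    decomposition, non-negative matrix factorization), and a self-tuning
    temperature-magnetization feedback that drives spontaneous symmetry
    breaking interpreted as cell differentiation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
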