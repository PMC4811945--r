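Package: spikesolve
Title: Stochastic Spiking Neural Networks for Constraint Satisfaction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Event-driven simulation of networks of stochastically firing
    spiking neurons with rectangular post-synaptic potentials, and tools for
    designing such networks through their Boltzmann energy function.  Provides
    winner-take-all, OR, and internal temperature-control circuit motifs,
    compilers that translate traveling-salesman instances and k-SAT formulas
    into spiking networks that perform stochastic search for low-energy
    (high-quality) solutions, a matched continuous-time Gibbs sampler
    (Boltzmann machine) baseline for comparing sampling dynamics, and readers
    and writers for TSPLIB and DIMACS CNF problem files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
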