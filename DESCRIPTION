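Package: operonet
Title: Mass-Action Models of Genetic Regulatory Networks from Interaction Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compiles a double graph of transcriptional activations and
    repressions into a mass-action reaction network under the Jacob-Monod
    operon model, with either one binding site per regulator or a single
    competitive site. Derives the polynomial rate equations, the
    stoichiometric matrix and all linear conservation laws (computed in
    exact rational arithmetic), integrates the resulting ODE systems,
    locates and classifies steady states, and scans conserved gene totals
    for the transcritical bifurcation that produces concentration
    thresholds. Includes tools to simulate spatial patterning from
    non-homogeneous regulator profiles along a one-dimensional axis
    (without diffusion), a builder for the Drosophila gap-gene
    hunchback/knirps cross-regulation model, synthetic anterior-posterior
    profile generators, and a genetic-algorithm calibrator minimizing
    chi-square against observed spatial profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    igraph,
    xml2,
    yaml,
    lhs,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
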