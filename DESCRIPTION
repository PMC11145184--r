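Package: hillbarrier
Title: Equilibrium Sharpness Limits of Input-Output Responses on Linear
    Framework Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the sharpness of steady-state input-output
    responses of biomolecular systems modelled as labelled directed graphs
    (continuous-time Markov processes in the linear framework). Computes
    exact steady states by the Matrix-Tree theorem, checks detailed balance
    via the cycle condition, coarse-grains arbitrary binding graphs onto
    hypercube substructures indexed by ligand-binding patterns, extracts the
    rational form of equilibrium responses, measures intrinsic position and
    steepness of a response, and estimates the universal position-steepness
    region attainable at thermodynamic equilibrium, whose boundary is set by
    the Hill function with coefficient equal to the number of binding sites.
    Nonequilibrium samplers demonstrate escape beyond this barrier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
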