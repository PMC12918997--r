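Package: dendband
Title: Working-Memory Models with Bistable Dendrites and Multistable
    Feedback Bands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis of attractor working-memory models in
    which graded stimulus amplitude is stored by recruiting bistable
    (hysteretic) dendritic compartments.  Implements a conductance-based
    spiking autapse neuron with ten NMDA/Kir bistable dendrites, a
    rate-based autapse with hysteretic latch units and the associated
    discrete and continuum multistable feedback bands, and a rate-based
    ring network that jointly stores the amplitude and location of a
    stimulus.  Includes analytic band approximations for the ring, a
    weight-design procedure for linear stimulus-to-memory mappings, and
    noise experiments measuring amplitude retention and bump-location
    diffusion.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
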