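Package: turingcost
Title: Energetics and Positional Accuracy of Self-Positioned Turing Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Thermodynamically consistent modelling of self-positioned Turing
    patterns in small biochemical systems. Implements a reversible three-species
    reaction-diffusion network (and a five-species MukBEF variant) on a 1-D
    no-flux lattice with an exact Gillespie simulator of the reaction-diffusion
    master equation, deterministic method-of-lines integration, linear-stability
    (dispersion/onset) analysis in infinite and finite systems, free-energy
    dissipation accounting (chemical and diffusive entropy production, cycle
    fluxes), and pattern metrics (stripe-peak tracking, positional error,
    phase-diffusion theory, error-energy fits, molecule-number robustness
    windows).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
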