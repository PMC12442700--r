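Package: surfdwell
Title: Run-and-Tumble Motility of Bacteria Near Solid Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Phenomenological model of Escherichia coli swimming near a
    solid surface. Simulates three-dimensional run-and-tumble trajectories
    with surface entrapment (clockwise circular surface runs, diffusive
    tumbles with steric hindrance), extracts surface residence times and
    their dependence on tumble bias, estimates the effective surface
    diffusivity from ensemble mean-squared displacements during residence
    periods, and evaluates a closed-form planar diffusivity derived from
    the corresponding Fokker-Planck description, including a curvature
    correction factor that reconciles the planar theory with the full
    three-dimensional simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
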