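Package: opticcup
Title: Spring-Based Vertex Model of Self-Driven Optic-Cup Morphogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Axisymmetric spring-based vertex model of the early optic
    vesicle. A meridional section of the retinal epithelium is discretized
    into quadrilateral elements joined by apical, basal, and transmural
    springs and evolved by overdamped gradient dynamics under three
    phase-scheduled local rules (neural-retina relaxation, hinge apical
    constriction, tangential growth). The package reproduces the
    relaxation-expansion mechanism of retinal morphogenesis: self-driven
    invagination of the neural retina inside the rigid retinal-pigment-
    epithelium shell, and evagination when the first two rules are omitted.
    Includes signed-curvature morphometrics, outcome classification,
    ggplot2 rendering, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    tibble,
    tidyr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
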