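Package: doepath
Title: In Silico Design-of-Experiments Evaluation for Combinatorial
    Pathway Optimization
Version: 0.1.0
Authors@R: person("doepath", "developers", role = c("aut", "cre"),
    email = "doepath@example.org")
Description: Simulates a full factorial strain library from a kinetic model
    of the seven-enzyme curcuminoid pathway and evaluates two-level
    design-of-experiments strategies for combinatorial pathway optimization:
    regular fractional factorial designs with their alias structure,
    Plackett-Burman screening designs and random sampling, analysed by
    ordinary-least-squares effect models and ANOVA, with optimal-strain
    prediction, robustness studies against noise and missing strains, and a
    random-forest baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
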