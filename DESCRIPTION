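Package: sterilopt
Title: Surrogate-Assisted Optimization of In Vitro Sterilization Protocols
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and optimizes surface-sterilization protocols for plant
    tissue culture from factorial dose-by-time screening data. Embeds the
    published treatment-mean tables of a chrysanthemum leaf-explant screen
    (six sterilants crossed with immersion times), reconstructs a
    replicate-level dataset from the printed means and standard errors,
    trains single-hidden-layer perceptron surrogates for contamination
    frequency and explant viability by Levenberg-Marquardt, optimizes each
    sterilant's concentration-by-time domain with an elitist non-dominated
    sorting genetic algorithm (NSGA-II), selects compromise protocols by
    ideal-point distance on the Pareto front, and ranks input importance by
    variable sensitivity ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
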