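Package: booldelay
Title: Time-Delayed Boolean Networks for Intracellular Signalling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Qualitative modelling of signal transduction with Boolean
    networks whose edges carry two integer dynamic parameters: a delayed
    activation (the minutes an input must be continuously on before it
    acts) and a sustained or delayed response (how long the effect outlasts
    the input, or how much extra accumulation it needs). Provides a rule
    language and parser, a synchronous minute-resolution simulator with
    in-silico knockouts and stimulus protocols, structural network
    analysis (linear-chain reduction, kernel-pathway and feedback-loop
    identification), maximum-entropy binarization of densitometry-style
    time courses, and a genetic-algorithm parameter fitter with two-stage
    kernel-first training.  Ships a fully parameterized model of the
    NF-kB inflammation network so its stimulation and knockout
    experiments can be reproduced in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
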