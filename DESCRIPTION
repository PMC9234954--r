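Package: whiskersim
Title: Closed-Loop Spiking Neural Network Simulator of the Rodent Whisker
    System with an Adaptive Cerebellar Controller
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Clock-driven leaky integrate-and-fire simulation of the
    peripheral rodent whisker system (trigeminal ganglion encoders,
    trigeminal nuclei, facial nuclei, central pattern generator), a
    lightweight torque-driven whisker plant with bar-contact stimuli, and a
    cerebellar microcircuit (mossy fibers, granule cells, Purkinje cells,
    inferior olive, deep cerebellar nuclei) with supervised parallel
    fiber-Purkinje cell plasticity. Runs closed-loop GO/NOGO whisking-based
    object-localization experiments comparing control and
    plasticity-impaired (L7-PP2B-like) genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
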