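Package: polychron
Title: Spiking Networks with Synaptic-Drive Metaplasticity and Polychronous
    Group Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Millisecond-resolution simulation of recurrent Izhikevich
    spiking networks with axonal conduction delays, additive spike-timing
    dependent plasticity (STDP), and a BCM-style metaplastic modification
    threshold driven by the per-synapse synaptic derivative ("synaptic
    drive"). Includes the experimental apparatus around the model: Poisson
    background input, patterned spatio-temporal stimuli, a
    maturation/training/probing protocol, response fingerprinting for
    polychronous neural group (PNG) detection, three-way weight censuses,
    connection-activation partitioning, and mechanistic microcircuit
    workbenches for spike latency, synaptic-drive reversal, and input-space
    analysis. Analysis functions are tibble-in/tibble-out; the simulation
    core is compiled C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
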