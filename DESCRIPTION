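Package: neuroregrow
Title: Homeostatic Structural Plasticity and Repair in Spiking Cortical Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates peripheral lesions and activity-dependent rewiring in
    balanced excitatory/inhibitory spiking cortical networks. Neurons grow and
    retract synaptic elements according to calcium-dependent Gaussian growth
    curves while inhibitory spike-timing-dependent plasticity maintains the
    excitation/inhibition balance. Provides the network constructor (jittered
    toroidal lattice, distance-dependent wiring, lesion-projection-zone
    labelling), a fast conductance-based integrate-and-fire engine, the
    structural-plasticity connectivity update (element bookkeeping,
    distance-kernel synapse formation, weight-dependent deletion with an
    immunity threshold), experiment protocols (balancing, deafferentation,
    growth-regime batteries, single-neuron homeostasis), and spike-train and
    connectivity analysis metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
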