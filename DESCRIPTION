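Package: hspsim
Title: Spiking Network Simulator with Homeostatic Structural Plasticity for
    Modeling tDCS and Motor Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clock-driven simulation of an inhibition-dominated recurrent
    network of leaky integrate-and-fire neurons in which excitatory-to-
    excitatory synapses are rewired by a homeostatic structural plasticity
    rule: each neuron senses its own activity through a calcium trace and
    grows or retracts axonal boutons and dendritic spines toward a firing-
    rate setpoint, and free elements pair randomly into new synapses.
    Includes protocols for motor-learning input to an engram subpopulation
    and transcranial direct-current stimulation (tDCS) with uniform,
    targeted, and unfocused electrode montages applied before, during, or
    after learning, plus connectivity-based readouts (block connectivity,
    engram strength, rate time series) and a parameter-sweep pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
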