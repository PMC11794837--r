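Package: pvgamma
Title: Spiking-Network Simulation of Gamma-Band Entrainment Under Inhibitory Maturation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based leaky integrate-and-fire network model of an
    excitatory pyramidal / parvalbumin-positive interneuron circuit with a
    long-tailed (truncated lognormal) distribution of excitatory postsynaptic
    potentials and stochastic transmission failure. Simulates spontaneous and
    periodically driven (gamma-band) activity, and quantifies stimulus
    entrainment by inter-trial phase coherence (ITPC) of population firing
    rates and by trial-averaged power spectra. Includes parameter sweeps over
    inhibitory and excitatory synaptic weights, input strength, and the EPSP
    truncation threshold, and a synthetic-signal generator with known
    ground-truth coherence for validating the analysis stage.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
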