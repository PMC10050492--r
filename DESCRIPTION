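Package: thetaring
Title: Spiking Ring Attractor Network with Intrinsic Theta Oscillation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a one-dimensional continuous-attractor network of
    leaky integrate-and-fire principal cells and interneurons connected
    through NMDA- and GABA-conductance synapses on a ring, in which a
    theta-band (4-12 Hz) oscillation arises intrinsically from the
    excitatory-inhibitory feedback loop. Provides the full analysis suite
    for the model: a local-field-potential proxy built from the delayed
    inhibitory currents onto principal cells, Welch power spectra with
    theta-peak metrics, population-activity-vector tracking of bump
    attractors and their drift, bump-profile statistics (height, width,
    sharpness), and Rayleigh-vector spike-phase locking to the field
    rhythm or to rhythmic septal input. Multi-trial protocols and
    parameter sweeps (synaptic time constants, septal drive, interneuron
    suppression, rhythmic input resonance) are orchestrated with seeded,
    reproducible random-number streams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
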