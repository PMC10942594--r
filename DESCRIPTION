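Package: thetanest
Title: Hybrid Septo-Hippocampal Model of Theta-Nested Gamma Oscillations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the generation of theta-nested gamma oscillations in a
    hippocampal-formation network driven by a medial-septum theta pacemaker.
    The medial septum is modelled as an ensemble of coupled Kuramoto phase
    oscillators with a biphasic phase-response function that mediates theta
    phase reset by CA1 feedback; the hippocampal formation (EC, DG, CA3, CA1)
    is a spatially embedded network of single-compartment conductance-based
    excitatory and inhibitory neurons (Na, K, Ca, CAN and M currents) coupled
    by biexponential conductance synapses. Includes intracellular stimulation
    protocols (single pulses, phase-targeted pulses, pulse trains), a
    sequential gain-tuning procedure, a Wilson-Cowan neural-mass variant of
    the same loop, and an oscillation-analysis stack: instantaneous firing
    rates, Welch power spectra with Simpson band power, short-time Fourier
    spectrograms, the Tort modulation index with uniform-noise correction,
    comodulograms, preferred-phase profiles and phase-response curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
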