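Package: ctcstim
Title: Closed-Loop Phase-Targeted Stimulation of Gamma-Oscillating Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates interneuron-gamma (ING) cortical columns built from
    conductance-based quadratic integrate-and-fire neurons, including a bistable
    three-column network implementing selective signal routing through
    coherence (CTC). Provides offline (Hilbert) and real-time
    (autoregressive-forecast) instantaneous gamma-phase tracking, Morlet
    wavelet spectral coherence with surrogate chance levels for measuring
    input-signal content, stochastic phase-response-curve and
    state-switch-probability estimation from paired pulsed/control
    simulations, drive-rate calibration, and closed-loop controllers that use
    single precisely timed current pulses to hold the network in a desired
    synchronization or routing state.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
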