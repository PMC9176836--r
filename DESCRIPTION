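Package: thermosync
Title: Quantifying AFD-AIY Calcium Synchrony and Thermotaxis Behavior in C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for simultaneous two-neuron calcium imaging in
    Caenorhabditis elegans thermosensation. Implements delta-F/F0 rescaling,
    zero-phase Butterworth detrending, a piecewise cross-correlation with
    zero-lag and lag-at-maximum synchrony statistics, Hamming-windowed Fourier
    power spectra with a cumulative-power signal/noise split and per-frequency
    SNR, a moving-average response-onset readout against a thermal ramp, and
    thermotaxis-plate scoring (8-section fractions and thermotaxis index).
    A synthetic-data module simulates ramped oscillatory thermal stimuli,
    threshold-gated AFD responses, AIY traces with controllable AFD coupling,
    and dispersing plate-count time courses, so that every analysis stage can
    be validated against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
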