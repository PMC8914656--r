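Package: betadrive
Title: Digital Twin, Metrology and Beta-Band Stress Analysis for a
    Six-Channel EEG Headband
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete software counterpart of a six-channel dry-electrode
    EEG headband and its driving-stress analysis chain.  Models the analog
    front-end (band-pass amplifier transfer function) and the oversampling
    analog-to-digital conversion scheme, computes the sensor noise budget and
    effective resolution, and implements a GUM-style metrological
    characterization (least-squares gain, uncertainty propagation, linearity,
    bandwidth, power-line notch rejection).  Downstream, it generates
    synthetic multichannel EEG cohorts with known band powers and artifacts,
    cleans recordings with an FIR band-pass, a simplified artifact-subspace
    reconstruction and ICA component removal, estimates Welch band powers,
    and compares beta-band power between driving conditions with
    nonparametric rank tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
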