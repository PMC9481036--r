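Package: rfcomp
Title: RF Pulse Distortion Compensation for Narrow-Band Transmit Coils
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for compensating radiofrequency (RF) pulse distortion in
    high quality-factor, low-frequency transmit coils such as those used in
    low-field magnetic resonance imaging. Estimates the coil quality factor
    from ring-down traces or bandwidth measurements, computes pre-emphasis and
    active-damping square pulses, synthesizes multi-square compensation trains
    that force the coil envelope through arbitrary sampled targets (for
    example sinc pulses for slice-selective excitation), simulates the coil
    response with both a first-order envelope model and a full second-order
    series-circuit model, and scores excitation profiles with an in-band
    spectral flatness metric.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
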