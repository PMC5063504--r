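Package: tncfret
Title: Analysis of Troponin C FRET Sensor Spectra and Divalent-Cation Titrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts raw fluorescence emission spectra of a troponin C
    (TnC)-based CFP/YFP FRET sensor into a FRET-ratio statistic by linear
    spectral unmixing with acceptor direct-excitation correction; fits Hill,
    double-Hill and Gaussian sedimentation-peak models to titration and
    analytical-ultracentrifugation data; computes free and bound metal
    concentrations in multi-chelator buffers; and decomposes the FRET signal
    into per-EF-hand contributions from site-inactivation mutant panels. A
    seeded synthetic fluorometer generates every input with known ground
    truth so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
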