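Package: cmrT2map
Title: Simulation and Analysis of T2-Prepared Myocardial T2 Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative myocardial T2 mapping with T2-prepared
    single-shot sequences. Synthesizes ground-truthed digital cardiac phantoms
    (partial-volume mixing, residual diastolic in-plane motion, Rician noise,
    FLASH-centric versus SSFP-linear readout transients), fits pixel-wise
    mono-exponential T2 maps and multi-echo spin-echo reference curves,
    performs AHA six-segment and edema-versus-remote analysis with
    microvascular-obstruction exclusion, measures residual diastolic wall
    motion from M-mode-like cine projections, and computes test-retest
    agreement statistics (Bland-Altman, interscan coefficient of variation,
    normal tolerance intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    pracma,
    minpack.lm,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
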