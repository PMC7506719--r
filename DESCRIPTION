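Package: earoximetry
Title: In-Ear and Finger Pulse Oximetry Analysis from Dual-Wavelength PPG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating peripheral blood oxygen saturation (SpO2)
    from dual-wavelength (red/infrared) reflective photoplethysmography (PPG)
    recorded simultaneously at the ear canal and the index finger. Implements
    the AC-envelope/DC ratio-of-ratios SpO2 extraction chain (band-pass AC
    isolation, prominence-based peak and trough detection, envelope
    interpolation, 0.01 Hz DC baseline, linear calibration), button-anchored
    breath-hold segmentation with site-specific desaturation-delay estimation,
    and cohort-level agreement, amplitude, and delay statistics. Includes a
    synthetic dual-site PPG cohort generator with known ground truth for
    end-to-end validation, tidy data interfaces, ggplot2 visualisations, and a
    reproducible simulate-extract-analyse pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
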