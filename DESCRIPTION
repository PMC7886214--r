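Package: mitralflow
Title: Transmitral Flow Energetics from Particle Image Velocimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-vitro style analysis pipeline for transmitral flow:
    synthetic pulse-duplicator data generation (kinematic inflow-jet fields,
    tracer-particle image pairs, left-atrial/left-ventricular pressure traces,
    continuous-wave Doppler envelopes), planar particle image velocimetry by
    multi-pass FFT cross-correlation with subpixel peak fitting and
    normalized-median vector validation, viscous energy dissipation (VED) of
    the planar velocity field and its time integral (TVED), transmitral
    pressure gradients from catheter traces and from Doppler envelopes via the
    simplified Bernoulli relation, and mitral valve area by the Gorlin
    equation. Results are tibbles designed for piped workflows, with ggplot2
    autoplot methods and broom-style tidiers.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
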