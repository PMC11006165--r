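Package: earmech
Title: Middle-Ear Transfer Functions, Ossicular Kinematics and Group Delays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparative middle-ear biomechanics from laser-Doppler
    vibrometry data. Provides a lumped-element simulator of umbo, incus and
    stapes velocity responses to ear-canal sound pressure; rotation-matrix
    composition and projection of 3D velocity components onto anatomical
    piston directions; transfer-function arithmetic on complex spectra
    (pressure normalisation, ossicular ratios, phase unwrapping, dB
    conversion, group averaging); group-delay estimation from unwrapped phase
    with acoustic propagation corrections; and micro-CT morphometry
    arithmetic (eardrum area and mass, ossicle masses, lever ratios,
    comparative size ratios). All user-facing functions take and return tidy
    data frames so pipelines compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
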