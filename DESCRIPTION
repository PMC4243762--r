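Package: probekit
Title: Photophysical Characterization of Solvatochromic Membrane Probes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for laurdan-family solvatochromic membrane
    probes. Computes generalized polarization (GP) from two-channel
    intensities, emission spectra and two-photon image stacks; relative
    quantum yields against a reference standard; radiative and
    non-radiative de-excitation rate constants and molecular brightness;
    fits time-correlated single-photon counting (TCSPC) decays as sums of
    exponentials with optional instrument-response reconvolution and
    reports intensity-weighted mean lifetimes; G-factor-corrected
    steady-state anisotropy and Perrin-Weber rotational relaxation times;
    dioxane/water dielectric mixtures, Lippert-Mataga orientational
    polarizability and Lippert regression; sigmoidal melting-transition
    fits of GP(T)/r(T) scans and one-site probe-insertion kinetics.
    Seeded synthetic-data generators emulate the spectrofluorimeter, the
    TCSPC instrument, the polarization accessory and the two-photon
    microscope so that every stage of the pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
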