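Package: fnirsms
Title: Motion-Sickness Classification from Multiband Spectral Entropy of fNIRS Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for classifying passenger motion sickness from
    prefrontal functional near-infrared spectroscopy (fNIRS) recordings.
    Converts dual-wavelength light intensities to oxy-/deoxyhemoglobin
    concentration changes via the modified Beer-Lambert law, suppresses motion
    artifacts by wavelet-coefficient thresholding, selects the dominant channel
    by principal component analysis, decomposes the signal into five
    physiological frequency bands (cardiac, respiratory, myogenic, neurogenic,
    endothelial) with a nine-level Daubechies-5 discrete wavelet transform,
    extracts normalized power-spectral-entropy features per band, and evaluates
    a radial-basis-function support vector machine under k-fold
    cross-validation. Includes a seeded synthetic study generator so the whole
    chain is testable without access to the original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
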