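Package: punctatrack
Title: Single-Particle Localization, Tracking and Activity Analysis of
    Membrane Channel Puncta
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing diffraction-limited fluorescent puncta of
    membrane ion channels (such as PIEZO1) in TIRF and lightsheet movies:
    sub-pixel spot localization with Gaussian PSF fitting, nearest-neighbour
    trajectory linking with gap closing, mobility quantification (single lag
    displacements, path-length classification, mean squared displacement and
    diffusion coefficients), photobleaching and localization-error estimation,
    single-channel optical flicker analysis with all-points amplitude
    histograms, and distance-transform spatial statistics of puncta in
    organoids with a central lumen. A synthetic-movie generator produces
    ground-truth-annotated TIRF-like movies and organoid scenes so that every
    analysis stage can be validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    tiff,
    png,
    yaml,
    jsonlite,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
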