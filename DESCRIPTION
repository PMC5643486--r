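Package: angiodyn
Title: Quantitative Dynamics of Video Fluorescein Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pixel-by-pixel quantification of dye-transit dynamics in video
    fluorescein angiography of the retina and cortical surface vasculature.
    Computes per-pixel half-rise, half-fall and offset (remnant fluorescence)
    maps from registered video stacks, classifies vessels into arteries,
    veins and the capillary/extravascular compartment by fill timing,
    and summarises barrier leakage with histogram, median/IQR, bootstrap
    confidence-limit and index-of-injury statistics. Includes a seedable
    synthetic angiography simulator (gamma-variate bolus transit with a
    saturating leakage plateau, camera noise and rigid motion) with full
    ground truth, so the pipeline can be validated end to end without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
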