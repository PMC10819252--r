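Package: chlorospec
Title: Optimal Two-Band Vegetation Indices for Leaf Chlorophyll Estimation
    from Hyperspectral Reflectance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates leaf chlorophyll content (LCC, micrograms per square
    centimetre) from laboratory hyperspectral reflectance imagery. Provides
    ENVI-style data-cube input/output, wavelength calibration by Lorentzian
    emission-line fitting, reflectance calibration against white and dark
    references, NDVI-threshold leaf segmentation, conversion of DMF-extract
    spectrophotometric absorbances (647 and 664 nm) to LCC, two-band
    vegetation indices (simple ratio, normalised difference, chlorophyll
    index, GNDVI), an exhaustive cross-validated band-pair regression search
    over 450-800 nm with moment-centroid optimal-band selection, a two-band
    linear LCC prediction model with per-pixel chlorophyll mapping, and a
    seeded synthetic leaf-spectrum generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
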