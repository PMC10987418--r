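Package: hospect
Title: Scatter Correction, Reconstruction and Voxel Dosimetry for Holmium-166 SPECT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for quantitative holmium-166
    single-photon emission computed tomography (SPECT) in selective internal
    radiotherapy. Builds digital Jaszczak-style sphere phantoms, simulates
    multi-energy-window projection acquisitions from a parametric model of the
    Ho-166 energy-spectrum components (photopeak plus associated scatter,
    high-energy downscatter, characteristic X-ray and bremsstrahlung
    contributions), applies dual-energy-window (DEW) and triple-energy-window
    (TEW) scatter corrections in projection space, reconstructs with
    ordered-subset expectation maximization (OSEM) including attenuation
    correction and an optional Butterworth post-filter, scores image quality
    with contrast recovery coefficients (CRC), sigmoid CRC-curve fits and
    contrast-to-noise ratios (CNR), and quantifies the dosimetric impact with
    local-dose-deposition compartment dosimetry, activity planning and paired
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
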