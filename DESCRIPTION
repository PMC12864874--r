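Package: shir
Title: Spatial Harmonic Imaging: Multicontrast X-Ray Retrieval and CT Preparation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing framework for single-shot spatial harmonic X-ray imaging
    with a two-dimensional periodic mask (inverted Hartmann mask). Takes raw
    dark, bright, reference (mask only) and sample (mask plus object) detector
    frames and retrieves absorption, differential-phase and scattering
    (dark-field) contrast images by Fourier-domain harmonic extraction, with
    automatic harmonic peak detection and band-limited filtering. Includes
    flat-field correction, corrupted-frame screening, cone-to-parallel sinogram
    rebinning, parallel-beam filtered backprojection with a Ram-Lak filter,
    reconstruction quality metrics (NRMSE, PSNR, MSSIM, NMI), and a synthetic
    Hartmann-mask forward simulator so the whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
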