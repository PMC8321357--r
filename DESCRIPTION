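Package: mrisr
Title: Unsupervised Denoising and Super-Resolution of Magnetic Resonance Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Patch-based low-rank denoising and single-image super-resolution
    for magnetic resonance (MR) slices and volumes, with no training data and
    no prior knowledge of the noise variance. Patches are clustered, projected
    on per-cluster eigenbases, and categorized as smooth or textured from the
    statistics of their low-rank reconstruction errors; the two kinds are
    denoised with different strategies. The denoiser is embedded in a sparse
    representation super-resolution loop that builds PCA dictionaries from a
    self-similarity pyramid, reconstructs low-frequency content by non-local
    means, regularizes edges with a gradient-profile-sharpness (GPS) prior
    estimated from a piecewise-linear LR-to-HR relation, and back-projects
    against the observed low-resolution image. Includes a forward degradation
    simulator (Gaussian PSF, decimation, Gaussian/Rician noise), brain-like
    phantom generation, and PSNR/SSIM/FSIM quality metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
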