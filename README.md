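# mrisr

Unsupervised denoising and single-image super-resolution for magnetic
resonance (MR) images, in R. No training data, no example images, and no
prior knowledge of the noise variance are required — everything is
estimated from the input image itself.

## Who this is for

Researchers working with structural MR volumes (or any piecewise-smooth
grayscale imagery) who need to improve SNR and apparent resolution as a
post-processing step: simulation studies of acquisition protocols,
preprocessing before segmentation or morphometry, and method development
against a transparent, fully scriptable baseline.

## The method

**Denoising.** Every overlapping 5×5 patch is split into its mean (LF) and
zero-mean remainder (HF). HF patches are clustered by k-means and each
cluster gets a PCA eigenbasis. The rank-l low-rank approximation (LRA)
error of patch j,

    e_j = || x_hj − x̂_hj ||²  =  Σ_{i>l} c_i²     (orthonormal basis),

concentrates near the noise floor for smooth patches and above it for
textured/edge patches, and its ensemble mean κ grows linearly with the
noise variance — an unsupervised noise proxy. Patches are categorized by
the band rule: *textured* iff τ1 < e_j < τ2 with τ1 = 0.7·κ, τ2 = 1.8·κ_c
(cluster-anchored), *smooth* otherwise. Smooth patches are averaged;
textured ones are replaced by their LRA; three rounds re-estimate the
eigenvectors from the denoised patches while reconstructing the original
data.

**Super-resolution.** Under the degradation model y = BHx (Gaussian PSF,
decimation), the HR estimate is refined iteratively: LF content by
non-local means, HF content by hard-thresholded sparse coding in
per-cluster PCA dictionaries built from a self-similarity pyramid of the
image itself, a gradient-profile-sharpness (GPS) prior that pushes edge
profiles toward a piecewise-linearly predicted HR sharpness
(η̂_H,i = β_i·η_U,i over four quantile regions, β_i fitted by Chi-squared
histogram matching between LR and upsampled-LR GPS distributions, weight
λ = 0.001), the embedded denoiser, and back projection through the exact
adjoint of BH.

**Metrics.** PSNR, SSIM (11×11 Gaussian window) and FSIM (log-Gabor phase
congruency + Scharr gradient similarity) are included for evaluation.

## Worked example

```r
library(mrisr)

ph <- make_phantom(c(96, 96), seed = 1)          # brain-like ground truth
model <- degradation_model(factor = 2, psf_sigma = 1)
y <- degrade(ph, model)                          # 48x48 LR observation
y <- add_gaussian_noise(y, noise_spec("gaussian", 0.02, seed = 1))

hr <- super_resolve(y, sr_config(factor = 2, max_iter = 8, seed = 1))
sp <- interp_resize(y$data, c(96, 96), align = "decimation")

psnr(ph, hr)        # 32.9 dB  — embedded SR + denoising
psnr(ph$data, sp)   # 30.7 dB  — cubic-spline interpolation
quality_report(ph, hr)
# $psnr 32.9  $ssim 0.816  $fsim 0.845
```

On the noiseless protocol (degrade only, no added noise) the same call
reaches ~42.0 dB against ~33.5 dB for spline interpolation.

A thin command-line front end with subcommands `simulate`, `denoise`,
`superres`, `evaluate` and `bench` is installed under `inst/cli/mrisr`:

```sh
Rscript inst/cli/mrisr simulate --out lr.nii.gz --factor 2 --percent 0.02
Rscript inst/cli/mrisr superres --input lr.nii.gz --out hr.nii.gz --factor 2
Rscript inst/cli/mrisr evaluate --reference truth.nii.gz --test hr.nii.gz
```

See `vignettes/mrisr-methods.Rmd` for the full model description, the
parameter defaults and their rationale, and known limitations.

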