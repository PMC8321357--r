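#' Degradation model y = B H x
#'
#' The forward model relating a high-resolution image `x` to its observed
#' low-resolution counterpart: a Gaussian point-spread function `H`
#' (standard deviation `psf_sigma` voxels, symmetric boundary) followed by a
#' decimation operator `B` that keeps every `factor`-th sample starting at
#' the first. The default PSF width of one voxel matches the standard MR
#' super-resolution simulation protocol.
#'
#' @param factor integer downsampling factor (>= 1), identical on all axes.
#' @param psf_sigma Gaussian PSF standard deviation in voxels (>= 0),
#'   default 1.
#' @return an object of class `mrisr_degradation`.
#' @export
degradation_model <- function(factor = 2L, psf_sigma = 1) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be an integer >= 1")
  if (psf_sigma < 0) stop("psf_sigma must be >= 0")
  structure(list(factor = factor, psf_sigma = psf_sigma, boundary = "symmetric"),
            class = "mrisr_degradation")
}

#' Noise specification
#'
#' Percent noise is defined against the volume's recorded peak intensity:
#' a level of `percent` means the noise standard deviation is
#' `sigma = percent * peak` (2% noise on a peak-255 image gives sigma 5.1).
#'
#' @param kind `"gaussian"` or `"rician"`.
#' @param percent noise level as a fraction of the peak (0.02 = 2%).
#' @param seed integer RNG seed; the noise field is deterministic given it.
#' @return an object of class `mrisr_noise`.
#' @export
noise_spec <- function(kind = c("gaussian", "rician"), percent = 0.02, seed = 1L) {
  kind <- match.arg(kind)
  if (percent < 0) stop("noise percent must be >= 0")
  structure(list(kind = kind, percent = percent, seed = as.integer(seed)),
            class = "mrisr_noise")
}

#' Add white Gaussian noise
#'
#' Adds a zero-mean white Gaussian field with standard deviation
#' `spec$percent * vol$peak`. Deterministic for a fixed seed; a zero percent
#' returns the input untouched.
#'
#' @param vol a [volume()] (or bare array, peak 255 assumed).
#' @param spec a [noise_spec()] with `kind = "gaussian"`.
#' @return a `mrisr_volume`.
#' @export
add_gaussian_noise <- function(vol, spec) {
  vol <- as_volume(vol)
  if (spec$kind != "gaussian") stop("spec$kind must be 'gaussian'")
  if (spec$percent == 0) return(vol)
  sigma <- spec$percent * vol$peak
  n <- length(vol$data)
  noise <- withr_seed(spec$seed, stats::rnorm(n, sd = sigma))
  vol$data <- vol$data + array(noise, dim = dim(vol$data))
  vol
}

#' Add Rician noise
#'
#' Magnitude-image noise: the output is `sqrt((x + n1)^2 + n2^2)` with `n1`,
#' `n2` independent zero-mean Gaussian fields of standard deviation
#' `percent * peak` -- the standard complex-Gaussian-magnitude construction.
#' At zero signal this reduces to a Rayleigh distribution; at high SNR it is
#' approximately Gaussian. Input intensities must be non-negative
#' (magnitude images only).
#'
#' @inheritParams add_gaussian_noise
#' @param spec a [noise_spec()] with `kind = "rician"`.
#' @return a `mrisr_volume` with non-negative intensities.
#' @export
add_rician_noise <- function(vol, spec) {
  vol <- as_volume(vol)
  if (spec$kind != "rician") stop("spec$kind must be 'rician'")
  if (any(vol$data < 0)) stop("Rician noise requires non-negative intensities")
  if (spec$percent == 0) return(vol)
  sigma <- spec$percent * vol$peak
  n <- length(vol$data)
  nn <- withr_seed(spec$seed, stats::rnorm(2 * n, sd = sigma))
  n1 <- array(nn[seq_len(n)], dim = dim(vol$data))
  n2 <- array(nn[n + seq_len(n)], dim = dim(vol$data))
  vol$data <- sqrt((vol$data + n1)^2 + n2^2)
  vol
}

# Run expr under a local RNG seed without disturbing the caller's RNG state.
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Apply the forward degradation y = B(H(x))
#'
#' Gaussian blur then decimation. Output spacing is the input spacing times
#' the factor; the peak is carried over.
#'
#' @param vol a [volume()] (or bare array).
#' @param model a [degradation_model()].
#' @return the degraded `mrisr_volume`.
#' @export
degrade <- function(vol, model = degradation_model()) {
  vol <- as_volume(vol)
  d <- dim(vol$data)
  if (any(d < model$factor)) stop("factor exceeds a spatial extent")
  blurred <- if (model$psf_sigma > 0) gaussian_blur(vol$data, model$psf_sigma) else vol$data
  volume(decimate(blurred, model$factor),
         spacing = vol$spacing * model$factor, peak = vol$peak)
}

#' Generate a brain-like piecewise-constant phantom
#'
#' Synthesizes a 2D slice (or 3D volume) made of nested elliptical regions
#' at distinct intensity levels over a zero background, each region boundary
#' smoothed by its own Gaussian blur drawn from `edge_blur_range`. The
#' result mimics the piecewise-constant tissue structure of T1 brain MR
#' slices: large flat interiors (smooth patches) and curved tissue
#' boundaries of varying sharpness (textured/edge patches). Deterministic
#' for a fixed seed.
#'
#' @param shape integer extents, length 2 or 3.
#' @param contrast_levels number of distinct intensity values including the
#'   background (>= 2); default 5 (background, CSF-, GM-, WM-like levels and
#'   one bright structure).
#' @param edge_blur_range numeric `(min, max)` of per-region boundary blur in
#'   voxels; default `c(0.5, 1.5)`.
#' @param seed integer RNG seed.
#' @param peak nominal peak intensity (default 255); levels are spread over
#'   `[0.25, 0.95] * peak`.
#' @return a `mrisr_volume`.
#' @export
make_phantom <- function(shape = c(128L, 128L), contrast_levels = 5L,
                         edge_blur_range = c(0.5, 1.5), seed = 1L, peak = 255) {
  shape <- as.integer(shape)
  if (length(shape) < 2L || length(shape) > 3L || any(shape[1:2] < 8L) ||
      (length(shape) == 3L && shape[3] < 1L)) {
    stop("shape must give 2 or 3 extents, in-plane extents >= 8")
  }
  if (contrast_levels < 2L) stop("contrast_levels must be >= 2")
  if (length(edge_blur_range) != 2L || any(edge_blur_range < 0)) {
    stop("edge_blur_range must be (min, max), both >= 0")
  }
  make2d <- function(seed2) {
    withr_seed(seed2, {
      nr <- shape[1]; nc <- shape[2]
      rr <- matrix(seq_len(nr), nr, nc)
      cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      img <- matrix(0, nr, nc)
      nshapes <- contrast_levels - 1L
      # order levels greedily so successively nested regions always differ
      # by a tissue-like contrast (adjacent iso-intense regions would give
      # edges indistinguishable from noise, which no tissue boundary does)
      pool <- seq(0.95, 0.25, length.out = nshapes) * peak
      levels <- pool[1]
      pool <- pool[-1]
      while (length(pool)) {
        nxt <- which.max(abs(pool - levels[length(levels)]))
        levels <- c(levels, pool[nxt])
        pool <- pool[-nxt]
      }
      # first region: large head-like ellipse; later regions nest inside it
      for (s in seq_len(nshapes)) {
        if (s == 1L) {
          c0 <- c(nr, nc) / 2 + stats::runif(2, -0.03, 0.03) * c(nr, nc)
          ax <- c(0.40 * nr, 0.36 * nc) * stats::runif(2, 0.95, 1.05)
        } else {
          c0 <- c(nr, nc) / 2 + stats::runif(2, -0.18, 0.18) * c(nr, nc)
          ax <- c(nr, nc) * stats::runif(2, 0.06, 0.22)
        }
        th <- stats::runif(1, 0, pi)
        x <- (rr - c0[1]) * cos(th) + (cc - c0[2]) * sin(th)
        y <- -(rr - c0[1]) * sin(th) + (cc - c0[2]) * cos(th)
        mask <- ((x / ax[1])^2 + (y / ax[2])^2 <= 1) * 1
        bl <- stats::runif(1, edge_blur_range[1], edge_blur_range[2])
        if (bl > 0) mask <- gaussian_blur(mask, bl)
        img <- img * (1 - mask) + levels[s] * mask
      }
      img
    })
  }
  if (length(shape) == 2L) {
    return(volume(make2d(seed), peak = peak))
  }
  arr <- array(0, dim = shape)
  for (s in seq_len(shape[3])) arr[, , s] <- make2d(seed + 7L * (s - 1L))
  volume(arr, peak = peak)
}

#' Generate a labeled flat/step-edge patch ensemble
#'
#' Builds a synthetic patch ensemble with known ground-truth structure for
#' studying the smooth/textured categorization: `n_flat` constant patches at
#' random tissue-like base intensities and `n_edge` oriented step-edge
#' patches (random orientation, offset within 1.5 px of the patch center,
#' step height drawn from `contrast_range` -- a gray-white-matter-like
#' boundary contrast band on the 0-255 scale). Gaussian noise at
#' `noise_percent` of the peak is added to every patch. Deterministic for a
#' fixed seed.
#'
#' @param n_flat,n_edge patch counts per class (defaults 500 each).
#' @param patch_size patch side length (default 5).
#' @param noise_percent Gaussian noise level (default 0.02).
#' @param contrast_range step-height range in intensity units
#'   (default c(50, 70)).
#' @param peak nominal peak intensity (default 255).
#' @param seed integer seed.
#' @return list with `ensemble` (a `mrisr_patches` ensemble) and
#'   `truth` (character vector, `"flat"`/`"edge"` per patch).
#' @export
make_labeled_patches <- function(n_flat = 500L, n_edge = 500L, patch_size = 5L,
                                 noise_percent = 0.02,
                                 contrast_range = c(50, 70), peak = 255,
                                 seed = 1L) {
  m <- patch_size^2
  withr_seed(seed, {
    n <- n_flat + n_edge
    P <- matrix(0, m, n)
    grid <- seq_len(patch_size) - (patch_size + 1) / 2
    rr <- matrix(grid, patch_size, patch_size)
    cc <- t(rr)
    base <- stats::runif(n, 0.2, 0.8) * peak
    for (j in seq_len(n_flat)) P[, j] <- base[j]
    for (j in seq_len(n_edge)) {
      th <- stats::runif(1, 0, pi)
      off <- stats::runif(1, -1.5, 1.5)
      h <- stats::runif(1, contrast_range[1], contrast_range[2])
      side <- (rr * cos(th) + cc * sin(th)) > off
      jj <- n_flat + j
      lo <- min(base[jj], peak - h)
      P[, jj] <- lo + h * as.vector(side)
    }
    P <- P + matrix(stats::rnorm(m * n, sd = noise_percent * peak), m, n)
    mu <- colMeans(P)
    ens <- new_patch_ensemble(hf = P - rep(mu, each = m), lf_mean = mu,
                              locations = cbind(rep(0L, n), rep(0L, n)),
                              patch_size = patch_size,
                              img_dim = c(patch_size, patch_size))
    list(ensemble = ens,
         truth = rep(c("flat", "edge"), c(n_flat, n_edge)))
  })
}
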