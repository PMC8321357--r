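#' Super-resolution configuration
#'
#' Parameters of the sparse-representation SR loop. The GPS weight
#' `lam = 0.001` and the iteration cap of 320 are the method's standard
#' operating point; `eps` stops the loop early once the relative Frobenius
#' change between successive HR estimates is insignificant (which typically
#' happens long before the cap).
#'
#' @param factor integer super-resolution factor (>= 1; >= 2 for real SR).
#' @param lam GPS regularization weight (default 0.001).
#' @param max_iter outer iteration cap (default 320).
#' @param eps relative-change convergence tolerance (default 1e-4).
#' @param coeff_threshold sparse-coding threshold: `"auto"` (per-cluster
#'   noise-floor proxy) or a fixed number.
#' @param pyramid_scales rescale factors of the self-similarity pyramid
#'   (default 0.75, 1, 1.25; the 1/factor downscale is always added).
#' @param nlm list with `search_radius`, `patch_radius`, `h` (`NULL` = data
#'   driven) for the low-frequency non-local means.
#' @param denoise a [denoise_config()] for the embedded denoiser.
#' @param noise_aware logical; `FALSE` disables the embedded denoiser (the
#'   disjoint ablation).
#' @param recluster logical; re-build clusters and dictionaries every
#'   iteration (default `TRUE`).
#' @param seed integer seed.
#' @return an object of class `mrisr_sr_config`.
#' @export
sr_config <- function(factor = 2L, lam = 0.001, max_iter = 320L, eps = 1e-4,
                      coeff_threshold = "auto",
                      pyramid_scales = c(0.75, 1, 1.25),
                      nlm = list(search_radius = 4L, patch_radius = 2L, h = NULL),
                      denoise = denoise_config(), noise_aware = TRUE,
                      recluster = TRUE, seed = 1L) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (eps <= 0) stop("eps must be > 0")
  if (lam < 0) stop("lam must be >= 0")
  structure(list(factor = factor, lam = lam, max_iter = as.integer(max_iter),
                 eps = eps, coeff_threshold = coeff_threshold,
                 pyramid_scales = pyramid_scales, nlm = nlm,
                 denoise = denoise, noise_aware = isTRUE(noise_aware),
                 recluster = isTRUE(recluster), seed = as.integer(seed)),
            class = "mrisr_sr_config")
}

#' Build per-cluster PCA dictionaries from a self-similarity pyramid
#'
#' HF patches are pooled from the image and its rescaled copies (the
#' self-similarity pyramid), clustered with k-means, and one orthonormal
#' PCA basis is fitted per cluster from that cluster's patches. Each
#' dictionary carries its cluster centroid (for routing new patches to
#' their nearest dictionary) and a per-cluster sparse-coding threshold: 3
#' times the median absolute training coefficient beyond the cluster's
#' 95%-energy rank, a data-driven noise-floor proxy.
#'
#' @param img numeric matrix (or 2D [volume()]).
#' @param scales numeric rescale factors (1 = the image itself).
#' @param k cluster count (`NULL` = automatic).
#' @param seed integer seed (interface stability; clustering is
#'   deterministic).
#' @param patch_size patch side length (default 5).
#' @return list of `mrisr_dictionary` objects (fields `atoms`, `values`,
#'   `centroid`, `threshold`).
#' @export
build_dictionaries <- function(img, scales = c(0.75, 1, 1.25), k = NULL,
                               seed = 1L, patch_size = 5L) {
  if (inherits(img, "mrisr_volume")) img <- img$data
  pool <- list()
  for (s in scales) {
    td <- round(dim(img) * s)
    if (any(td < patch_size)) next
    scaled <- if (all(td == dim(img))) img else interp_resize(img, td)
    pool[[length(pool) + 1L]] <- extract_patches(scaled, patch_size)$hf
  }
  if (!length(pool)) stop("empty patch pool: image too small at every scale")
  X <- do.call(cbind, pool)
  if (ncol(X) < 2L) stop("empty patch pool: image too small at every scale")
  if (is.null(k)) k <- default_k(ncol(X))
  fit <- lloyd_kmeans(X, as.integer(min(k, ncol(X))))
  dicts <- vector("list", max(fit$labels))
  for (j in seq_along(dicts)) {
    idx <- fit$labels == j
    Xj <- X[, idx, drop = FALSE]
    basis <- if (sum(idx) >= 2L) fit_eigenbasis(Xj) else fit_eigenbasis(X)
    l95 <- resolve_rank(basis, "auto")
    coef_tail <- crossprod(basis$vectors[, -seq_len(l95), drop = FALSE], Xj)
    thr <- 3 * stats::median(abs(coef_tail))
    dicts[[j]] <- structure(list(atoms = basis$vectors, values = basis$values,
                                 centroid = fit$centers[, j],
                                 threshold = thr),
                            class = "mrisr_dictionary")
  }
  dicts
}

# Nearest-centroid dictionary routing for columns of hf.
route_patches <- function(dicts, hf) {
  C <- vapply(dicts, function(d) d$centroid, numeric(nrow(hf)))
  d2 <- -2 * crossprod(hf, C) + colSums(hf^2)
  d2 <- sweep(d2, 2L, colSums(C^2), `+`)
  max.col(-d2, ties.method = "first")
}

#' Sparse-code an HF patch in a PCA dictionary
#'
#' Projects the patch on the dictionary atoms and zeroes coefficients of
#' magnitude below the threshold -- sparsity by hard thresholding, with the
#' reconstruction `atoms %*% coefficients`.
#'
#' @param patch_hf numeric vector (length m).
#' @param dict a `mrisr_dictionary`.
#' @param threshold hard threshold; defaults to the dictionary's own.
#' @return numeric coefficient vector of length m.
#' @export
sparse_code <- function(patch_hf, dict, threshold = dict$threshold) {
  a <- as.vector(crossprod(dict$atoms, patch_hf))
  a[abs(a) < threshold] <- 0
  a
}

# symmetric padding of a matrix by p pixels on every side
pad_symmetric <- function(img, p) {
  d <- dim(img)
  ri <- c(rev(seq_len(p)), seq_len(d[1]), d[1] - seq_len(p) + 1L)
  ci <- c(rev(seq_len(p)), seq_len(d[2]), d[2] - seq_len(p) + 1L)
  img[ri, ci, drop = FALSE]
}

# separable valid convolution of an (n+2r) x (m+2r) array with a 1-D kernel
# g (length 2r+1) along both axes, returning n x m
sep_valid_conv <- function(E, g) {
  r <- (length(g) - 1L) / 2L
  d <- dim(E)
  tmp <- matrix(0, d[1] - 2L * r, d[2])
  for (k in seq_along(g)) {
    tmp <- tmp + g[k] * E[(k):(d[1] - 2L * r + k - 1L), , drop = FALSE]
  }
  out <- matrix(0, d[1] - 2L * r, d[2] - 2L * r)
  for (k in seq_along(g)) {
    out <- out + g[k] * tmp[, (k):(d[2] - 2L * r + k - 1L), drop = FALSE]
  }
  out
}

#' Non-local means filtering
#'
#' Classic non-local means: each pixel becomes a convex combination of the
#' pixels in its search window, weighted by `exp(-d2/h^2)` where `d2` is the
#' Gaussian-weighted mean squared difference between the surrounding
#' patches; the center weight is the maximum neighbor weight. Borders are
#' handled by symmetric padding. With `h = NULL` the bandwidth is set from
#' the data as the median patch distance over the search window, so no
#' noise-variance input is needed. Used to reconstruct the low-frequency
#' component of the HR estimate.
#'
#' @param img numeric matrix or 2D [volume()].
#' @param search_radius half-width of the search window (default 4).
#' @param patch_radius half-width of the comparison patch (default 2).
#' @param h filter bandwidth; `NULL` for data-driven.
#' @return filtered matrix (bounded by the input min/max).
#' @export
nlm_lowfreq <- function(img, search_radius = 4L, patch_radius = 2L, h = NULL) {
  if (inherits(img, "mrisr_volume")) img <- img$data
  d <- dim(img)
  sr <- as.integer(search_radius); pr <- as.integer(patch_radius)
  P <- sr + pr
  ipad <- pad_symmetric(img, P)
  g1 <- exp(-((-pr:pr)^2) / (2 * max(pr / 2, 0.5)^2))
  g1 <- g1 / sum(g1)
  # region of the padded image on which squared differences are needed
  rows_e <- (P + 1L - pr):(P + d[1] + pr)
  cols_e <- (P + 1L - pr):(P + d[2] + pr)
  offs <- expand.grid(a = -sr:sr, b = -sr:sr)
  offs <- offs[!(offs$a == 0 & offs$b == 0), ]
  dists <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    a <- offs$a[i]; b <- offs$b[i]
    E <- (ipad[rows_e, cols_e] - ipad[rows_e + a, cols_e + b])^2
    dists[[i]] <- sep_valid_conv(E, g1)
  }
  if (is.null(h)) {
    samp <- unlist(lapply(dists, function(m) m[seq(1L, length(m), by = 11L)]))
    h2 <- max(stats::median(samp), 1e-12)
  } else {
    h2 <- h^2
  }
  num <- matrix(0, d[1], d[2])
  den <- matrix(0, d[1], d[2])
  wmax <- matrix(0, d[1], d[2])
  rows_c <- (P + 1L):(P + d[1]); cols_c <- (P + 1L):(P + d[2])
  for (i in seq_len(nrow(offs))) {
    w <- exp(-dists[[i]] / h2)
    num <- num + w * ipad[rows_c + offs$a[i], cols_c + offs$b[i]]
    den <- den + w
    wmax <- pmax(wmax, w)
  }
  wmax <- pmax(wmax, 1e-12)
  (num + wmax * img) / (den + wmax)
}

#' Back-projection step
#'
#' Enforces data fidelity to the observed LR image: the LR residual
#' `y - B H x` is lifted to the HR grid through the exact adjoint of the
#' degradation operator and added to the estimate, with the step halved (up
#' to 5 times) whenever the residual norm would increase; if no step
#' decreases it the estimate is returned unchanged.
#'
#' @param x_hat HR estimate (matrix or 2D [volume()]).
#' @param y observed LR image (matrix or 2D [volume()]).
#' @param model the [degradation_model()] relating them.
#' @param step initial step size (default `factor^2`, compensating the
#'   energy loss of decimation).
#' @return updated HR estimate (same type as `x_hat`).
#' @export
back_project <- function(x_hat, y, model, step = model$factor^2) {
  was_vol <- inherits(x_hat, "mrisr_volume")
  vol <- as_volume(x_hat)
  x <- vol$data
  yv <- if (inherits(y, "mrisr_volume")) y$data else y
  pred <- degrade(volume(x, peak = vol$peak), model)$data
  if (!all(dim(pred) == dim(yv))) stop("degrade(x_hat) and y shapes differ")
  r <- yv - pred
  r0 <- sum(r^2)
  if (r0 == 0) return(x_hat)
  up <- decimate_adjoint(r, model$factor, dim(x))
  g <- if (model$psf_sigma > 0) gaussian_blur_adjoint2(up, model$psf_sigma) else up
  s <- step
  for (i in 0:5) {
    cand <- x + s * g
    rc <- yv - degrade(volume(cand, peak = vol$peak), model)$data
    if (sum(rc^2) < r0) {
      vol$data <- cand
      return(if (was_vol) vol else cand)
    }
    s <- s / 2
  }
  x_hat
}

# one SR pass on a single 2D slice. The initial estimate is the denoised
# spline interpolation (denoising runs on the HR grid, where smooth-majority
# patch statistics hold; fixture-sized LR grids are too edge-dense for the
# noise-adaptive thresholds). Back projection enforces fidelity to the
# observed LR image between iterations; the returned estimate is the
# post-denoising average of the final iteration.
sr_slice <- function(y_lr, cfg, model) {
  f <- cfg$factor
  x <- spline_upsample(y_lr, f)
  if (cfg$noise_aware) x <- denoise_image(x, cfg$denoise)
  den_lr <- decimate(x, f)
  # GPS prior: LR map stands in for the HR distribution; UR map is corrected
  eta_L <- compute_gps_map(den_lr)
  eta_U <- compute_gps_map(x)
  target_gps <- NULL
  if (cfg$lam > 0 && any(eta_L$edge_mask) && any(eta_U$edge_mask)) {
    gains <- tryCatch(
      suppressWarnings(estimate_piecewise_gains(eta_L, eta_U)),
      error = function(e) NULL)
    if (!is.null(gains)) target_gps <- predict_hr_gps(eta_U, gains)
  }
  scales <- c(cfg$pyramid_scales, 1 / f)
  p <- cfg$denoise$patch_size
  m <- p^2
  dicts <- NULL
  for (it in seq_len(cfg$max_iter)) {
    if (is.null(dicts) || cfg$recluster) {
      dicts <- build_dictionaries(x, scales = scales, seed = cfg$seed,
                                  patch_size = p)
    }
    # LF by non-local means, HF by sparse coding in the routed dictionary
    lf_img <- nlm_lowfreq(x, cfg$nlm$search_radius, cfg$nlm$patch_radius,
                          cfg$nlm$h)
    ens <- extract_patches(x, p)
    lf_ens <- extract_patches(lf_img, p)
    lab <- route_patches(dicts, ens$hf)
    hf_new <- ens$hf
    for (j in unique(lab)) {
      idx <- lab == j
      A <- dicts[[j]]$atoms
      thr <- if (identical(cfg$coeff_threshold, "auto")) dicts[[j]]$threshold
             else cfg$coeff_threshold
      alpha <- crossprod(A, ens$hf[, idx, drop = FALSE])
      alpha[abs(alpha) < thr] <- 0
      hf_new[, idx] <- A %*% alpha
    }
    ens$hf <- hf_new
    ens$lf_mean <- lf_ens$lf_mean
    x_sr <- aggregate_patches(ens)
    attr(x_sr, "uncovered") <- NULL
    # GPS regularization, embedded denoising, averaging, back projection
    x8 <- if (!is.null(target_gps)) gps_regularize(x_sr, target_gps, cfg$lam)
          else x_sr
    x_est <- if (cfg$noise_aware) (x8 + denoise_image(x8, cfg$denoise)) / 2
             else x8
    # data fidelity to the observed LR image closes every iteration
    x_new <- back_project(x_est, y_lr, model)
    rel <- sqrt(sum((x_new - x)^2)) / max(sqrt(sum(x^2)), 1e-12)
    x <- x_new
    if (rel < cfg$eps) break
  }
  x
}

#' Super-resolve a noisy LR image
#'
#' The full unsupervised SR pipeline: the LR input is denoised (unless
#' `noise_aware = FALSE`) and spline-interpolated to the HR grid; the HR GPS
#' target is predicted from the piecewise-linear LR-to-UR GPS relation; then
#' each iteration reconstructs the low-frequency component by non-local
#' means and the high-frequency component by hard-thresholded sparse coding
#' in per-cluster PCA dictionaries built from a self-similarity pyramid,
#' applies the GPS regularization step, averages with the embedded
#' denoiser's output, and back-projects against the LR image, until the
#' estimate stops changing (relative change below `eps`) or `max_iter` is
#' reached. 3D volumes are processed slice by slice along the third axis.
#'
#' @param y observed LR image: a [volume()] or bare matrix/array.
#' @param cfg an [sr_config()].
#' @param model the assumed [degradation_model()]; defaults to a Gaussian
#'   PSF of one voxel and the configured factor.
#' @return the HR estimate as a `mrisr_volume` (spacing divided by the
#'   factor).
#' @export
super_resolve <- function(y, cfg = sr_config(),
                          model = degradation_model(cfg$factor, 1)) {
  vol <- as_volume(y)
  if (model$factor != cfg$factor) stop("model factor must match cfg$factor")
  d <- dim(vol$data)
  if (length(d) == 2L) {
    out <- sr_slice(vol$data, cfg, model)
    sp <- vol$spacing / cfg$factor
  } else {
    out <- array(0, dim = d * c(cfg$factor, cfg$factor, 1L))
    for (s in seq_len(d[3])) {
      out[, , s] <- sr_slice(vol$data[, , s], cfg, model)
    }
    sp <- vol$spacing / c(cfg$factor, cfg$factor, 1)
  }
  volume(out, spacing = sp, peak = vol$peak)
}
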