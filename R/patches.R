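#' Patch ensembles
#'
#' A `PatchEnsemble` holds all overlapping patches of a 2D slice in
#' vectorized form, split into their low-frequency (LF) and high-frequency
#' (HF) components: for a patch `x` with pixel mean `mu`, the LF part is the
#' constant vector `mu` and the HF part is `x - mu` (which sums to zero).
#' The HF matrix is stored with one patch per column (`m x N`,
#' `m = patch_size^2`), plus per-patch LF means, 0-based top-left locations
#' in raster order, optional cluster labels, and the source image extents.
#'
#' @name patch-ensemble
NULL

new_patch_ensemble <- function(hf, lf_mean, locations, patch_size, img_dim,
                               labels = NULL, stride = 1L) {
  structure(list(hf = hf, lf_mean = lf_mean, locations = locations,
                 labels = labels, patch_size = as.integer(patch_size),
                 img_dim = as.integer(img_dim), stride = as.integer(stride)),
            class = "mrisr_patches")
}

#' Extract overlapping patches from a 2D slice
#'
#' All `patch_size x patch_size` patches fully inside the image, taken with
#' the given stride in raster (row-major over 0-based top-left corners)
#' order, and split into LF mean and zero-mean HF component.
#'
#' @param img numeric matrix (or 2D [volume()]).
#' @param patch_size patch side length in pixels (default 5).
#' @param stride step between patch origins (default 1).
#' @return a `mrisr_patches` ensemble.
#' @export
extract_patches <- function(img, patch_size = 5L, stride = 1L) {
  if (inherits(img, "mrisr_volume")) img <- img$data
  d <- dim(img)
  patch_size <- as.integer(patch_size)
  stride <- as.integer(stride)
  if (any(d < patch_size)) stop("patch_size exceeds an image extent")
  if (stride < 1L) stop("stride must be >= 1")
  rows0 <- seq(0L, d[1] - patch_size, by = stride)
  cols0 <- seq(0L, d[2] - patch_size, by = stride)
  # raster order: row-major over (row0, col0)
  locs <- cbind(row = rep(rows0, times = length(cols0)),
                col = rep(cols0, each = length(rows0)))
  locs <- locs[order(locs[, 1], locs[, 2]), , drop = FALSE]
  m <- patch_size^2
  off <- as.vector(outer(seq_len(patch_size),
                         (seq_len(patch_size) - 1L) * d[1], `+`)) - 1L
  base <- locs[, 1] + locs[, 2] * d[1] + 1L
  idx <- outer(off, base, `+`)          # m x N linear indices
  P <- matrix(img[as.vector(idx)], nrow = m)
  mu <- colMeans(P)
  new_patch_ensemble(hf = P - rep(mu, each = m), lf_mean = mu,
                     locations = locs, patch_size = patch_size,
                     img_dim = d, stride = stride)
}

#' Split a patch vector into LF and HF components
#'
#' The LF component is the constant vector of the patch mean; the HF
#' component is the remainder and sums to zero.
#'
#' @param patch numeric vector.
#' @return list with `lf` and `hf`, each the length of `patch`.
#' @export
split_lf_hf <- function(patch) {
  mu <- mean(patch)
  list(lf = rep(mu, length(patch)), hf = patch - mu)
}

# Deterministic, order-invariant Lloyd k-means on columns of X (m x N).
# Initial centers are the patches at k norm quantiles, which makes the
# labeling invariant to input permutation (up to exact ties); empty clusters
# are re-seeded from the patch farthest from its center.
lloyd_kmeans <- function(X, k, iter_max = 30L) {
  N <- ncol(X)
  if (k > N) stop("k must not exceed the number of patches")
  if (k == 1L) return(list(labels = rep(1L, N), centers = rowMeans(X)))
  nrm <- colSums(X^2)
  ord <- order(nrm, 1 - seq_len(N) / N)  # stable; ties broken by raster order
  pick <- ord[unique(pmax(1L, round(seq(1, N, length.out = k))))]
  while (length(pick) < k) pick <- c(pick, ord[length(pick) + 1L])
  C <- X[, pick, drop = FALSE]
  labels <- integer(N)
  for (it in seq_len(iter_max)) {
    d2 <- -2 * crossprod(X, C)
    d2 <- d2 + nrm
    d2 <- sweep(d2, 2L, colSums(C^2), `+`)
    new_labels <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters from the globally farthest patch
    for (j in which(tabulate(new_labels, k) == 0L)) {
      far <- which.max(d2[cbind(seq_len(N), new_labels)])
      new_labels[far] <- j
      d2[far, ] <- -Inf  # keep it there this round
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (j in seq_len(k)) {
      C[, j] <- rowMeans(X[, labels == j, drop = FALSE])
    }
  }
  list(labels = labels, centers = C)
}

# Default cluster count for an ensemble of N patches.
default_k <- function(N) max(2L, min(64L, as.integer(round(sqrt(N) / 4))))

#' Cluster HF patches with k-means
#'
#' Euclidean-distance k-means on the HF components. The implementation is a
#' deterministic Lloyd iteration whose initialization depends only on patch
#' values (norm quantiles), so the labeling is reproducible and invariant to
#' patch ordering. Labels are integers in `[0, k)`.
#'
#' @param ensemble a `mrisr_patches` ensemble.
#' @param k number of clusters (default `max(2, round(sqrt(N)/4))`, capped
#'   at 64).
#' @param seed integer seed, kept for interface stability (the default
#'   initialization is deterministic and does not consume randomness).
#' @return the ensemble with `labels` filled.
#' @export
cluster_patches <- function(ensemble, k = NULL, seed = 1L) {
  N <- ncol(ensemble$hf)
  if (is.null(k)) k <- default_k(N)
  if (k > N) stop("k must not exceed the number of patches (", N, ")")
  fit <- lloyd_kmeans(ensemble$hf, as.integer(k))
  ensemble$labels <- fit$labels - 1L
  ensemble$centers <- fit$centers
  ensemble
}

#' Re-assemble an image from (possibly modified) patches
#'
#' Each pixel becomes the average of all patch values covering it (overlap
#' averaging). Pixels covered by no patch are filled with 0 and reported via
#' the `"uncovered"` attribute. Patch values are `hf + lf_mean`.
#'
#' @param ensemble a `mrisr_patches` ensemble.
#' @param shape target extents; defaults to the source image extents.
#' @return numeric matrix of the requested shape.
#' @export
aggregate_patches <- function(ensemble, shape = ensemble$img_dim) {
  p <- ensemble$patch_size
  m <- p^2
  if (any(ensemble$locations < 0) ||
      any(ensemble$locations[, 1] + p > shape[1]) ||
      any(ensemble$locations[, 2] + p > shape[2])) {
    stop("patch locations out of bounds for the requested shape")
  }
  vals <- ensemble$hf + rep(ensemble$lf_mean, each = m)
  accum <- matrix(0, shape[1], shape[2])
  count <- matrix(0, shape[1], shape[2])
  off <- as.vector(outer(seq_len(p), (seq_len(p) - 1L) * shape[1], `+`)) - 1L
  base <- ensemble$locations[, 1] + ensemble$locations[, 2] * shape[1] + 1L
  for (i in seq_len(m)) {
    idx <- base + off[i]  # distinct: one pixel per patch at a fixed offset
    accum[idx] <- accum[idx] + vals[i, ]
    count[idx] <- count[idx] + 1
  }
  out <- accum
  covered <- count > 0
  out[covered] <- out[covered] / count[covered]
  attr(out, "uncovered") <- sum(!covered)
  out
}
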