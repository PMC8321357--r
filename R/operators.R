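# Linear image operators: separable Gaussian blur with symmetric boundary,
# decimation, their exact adjoints, and cubic-spline resampling. The blur is
# realized as an explicit banded matrix per axis so that the adjoint of the
# composite degradation operator y = B H x is the exact matrix transpose --
# back projection relies on this.

# 1-D Gaussian convolution matrix (n x n) with symmetric (reflective,
# half-sample) boundary handling. sigma = 0 gives the identity.
gauss_conv_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(3.5 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (t in -r:r) {
    j <- (1:n) + t
    # symmetric reflection: ..., 2, 1 | 1, 2, ..., n | n, n-1, ...
    j <- ifelse(j < 1L, 1L - j, j)
    j <- ifelse(j > n, 2L * n + 1L - j, j)
    j <- pmin(pmax(j, 1L), n)
    K[cbind(1:n, j)] <- K[cbind(1:n, j)] + w[t + r + 1L]
  }
  K
}

#' Gaussian blur of a 2D or 3D array
#'
#' Separable Gaussian filtering with symmetric (reflective) boundary
#' handling. Used as the PSF `H` of the degradation model and as the smoother
#' inside the phantom generator and GPS regularizer.
#'
#' @param x numeric matrix or 3D array.
#' @param sigma blur standard deviation in voxels (scalar, or one per axis).
#' @return array of the same shape.
#' @export
gaussian_blur <- function(x, sigma) {
  d <- dim(x)
  nd <- length(d)
  sigma <- rep_len(sigma, nd)
  if (nd == 2L) {
    K1 <- gauss_conv_matrix(d[1], sigma[1])
    K2 <- gauss_conv_matrix(d[2], sigma[2])
    return(K1 %*% x %*% t(K2))
  }
  if (nd == 3L) {
    out <- x
    for (s in seq_len(d[3])) out[, , s] <- gaussian_blur(out[, , s], sigma[1:2])
    if (sigma[3] > 0) {
      K3 <- gauss_conv_matrix(d[3], sigma[3])
      m <- matrix(out, nrow = d[1] * d[2])
      out <- array(m %*% t(K3), dim = d)
    }
    return(out)
  }
  stop("gaussian_blur: need a 2D or 3D array")
}

# Adjoint of gaussian_blur (matrix transpose per axis), 2D.
gaussian_blur_adjoint2 <- function(x, sigma) {
  d <- dim(x)
  sigma <- rep_len(sigma, 2L)
  K1 <- gauss_conv_matrix(d[1], sigma[1])
  K2 <- gauss_conv_matrix(d[2], sigma[2])
  t(K1) %*% x %*% K2
}

# Decimation: every factor-th sample starting at index 1, each axis.
decimate <- function(x, factor) {
  d <- dim(x)
  if (length(d) == 2L) {
    x[seq(1L, d[1], by = factor), seq(1L, d[2], by = factor), drop = FALSE]
  } else {
    x[seq(1L, d[1], by = factor), seq(1L, d[2], by = factor),
      seq(1L, d[3], by = factor), drop = FALSE]
  }
}

# Adjoint of decimation: zero-filled upsampling onto grid of extents hi_dim.
decimate_adjoint <- function(x, factor, hi_dim) {
  out <- array(0, dim = hi_dim)
  d <- dim(x)
  if (length(hi_dim) == 2L) {
    out[seq(1L, by = factor, length.out = d[1]),
        seq(1L, by = factor, length.out = d[2])] <- x
  } else {
    out[seq(1L, by = factor, length.out = d[1]),
        seq(1L, by = factor, length.out = d[2]),
        seq(1L, by = factor, length.out = d[3])] <- x
  }
  out
}

# Separable cubic-spline resampling of a matrix onto an arbitrary grid of
# source coordinates (1-based, in source pixel units).
spline_resample_axis <- function(m, xout, along) {
  if (along == 1L) {
    apply(m, 2L, function(col) stats::spline(seq_along(col), col, xout = xout,
                                             method = "fmm")$y)
  } else {
    t(apply(m, 1L, function(row) stats::spline(seq_along(row), row, xout = xout,
                                               method = "fmm")$y))
  }
}

#' Cubic-spline resize of a 2D image
#'
#' Separable cubic-spline interpolation. Two grid conventions are provided:
#' `align = "decimation"` places low-resolution sample i at high-resolution
#' position (i-1)*factor + 1, matching the decimation operator of the
#' degradation model (this is the convention used to initialize the
#' super-resolution estimate); `align = "span"` maps the source extent
#' linearly onto the target extent (used for the self-similarity pyramid).
#'
#' @param img numeric matrix.
#' @param target_dim integer vector of length 2, the output extents.
#' @param align `"decimation"` or `"span"`.
#' @return matrix with dimensions `target_dim`.
#' @export
interp_resize <- function(img, target_dim, align = c("span", "decimation")) {
  align <- match.arg(align)
  d <- dim(img)
  grid_for <- function(n_src, n_out) {
    if (align == "decimation") {
      f <- n_out / n_src
      1 + (seq_len(n_out) - 1) / f
    } else if (n_out == 1L) {
      (1 + n_src) / 2
    } else {
      1 + (seq_len(n_out) - 1) * (n_src - 1) / (n_out - 1)
    }
  }
  out <- spline_resample_axis(img, grid_for(d[1], target_dim[1]), along = 1L)
  out <- matrix(out, nrow = target_dim[1])
  out <- spline_resample_axis(out, grid_for(d[2], target_dim[2]), along = 2L)
  matrix(out, nrow = target_dim[1], ncol = target_dim[2])
}

# Spline upsampling of an LR image by an integer factor on the decimation-
# aligned grid (the SR initializer and the baseline interpolator).
spline_upsample <- function(img, factor) {
  interp_resize(img, dim(img) * factor, align = "decimation")
}
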