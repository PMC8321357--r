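#' Peak signal-to-noise ratio
#'
#' `10*log10(peak^2 / MSE)` over all voxels; identical inputs give `Inf`.
#'
#' @param ref,test equal-shaped arrays or [volume()]s.
#' @param peak peak intensity; defaults to the reference's recorded peak
#'   (255 for bare arrays).
#' @return decibels (possibly `Inf`).
#' @export
psnr <- function(ref, test, peak = NULL) {
  if (is.null(peak)) peak <- if (inherits(ref, "mrisr_volume")) ref$peak else 255
  r <- if (inherits(ref, "mrisr_volume")) ref$data else ref
  t <- if (inherits(test, "mrisr_volume")) test$data else test
  if (!all(dim(r) == dim(t))) stop("psnr: shapes differ")
  mse <- mean((r - t)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

# 1-D Gaussian window, normalized
gauss_win <- function(size = 11L, sigma = 1.5) {
  r <- (size - 1L) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g / sum(g)
}

ssim_slice <- function(r, t, peak) {
  g <- gauss_win()
  win <- 11L
  if (any(dim(r) < win)) stop("ssim: image smaller than the 11x11 window")
  C1 <- (0.01 * peak)^2
  C2 <- (0.03 * peak)^2
  f <- function(x) sep_valid_conv(x, g)
  # sep_valid_conv expects a border of (win-1)/2 around the output region:
  # here the "padded" input is the image itself and the output the valid area
  mur <- f(r); mut <- f(t)
  sr2 <- f(r * r) - mur^2
  st2 <- f(t * t) - mut^2
  srt <- f(r * t) - mur * mut
  num <- (2 * mur * mut + C1) * (2 * srt + C2)
  den <- (mur^2 + mut^2 + C1) * (sr2 + st2 + C2)
  mean(num / den)
}

#' Structural similarity index
#'
#' Standard windowed SSIM: 11x11 Gaussian window of sigma 1.5, stabilizers
#' `C1 = (0.01*peak)^2`, `C2 = (0.03*peak)^2`, averaged over all windows
#' fully inside the image. 3D volumes are scored slice-wise along the third
#' axis and averaged.
#'
#' @inheritParams psnr
#' @return scalar in `[-1, 1]`; 1 for identical inputs.
#' @export
ssim <- function(ref, test, peak = NULL) {
  if (is.null(peak)) peak <- if (inherits(ref, "mrisr_volume")) ref$peak else 255
  r <- if (inherits(ref, "mrisr_volume")) ref$data else ref
  t <- if (inherits(test, "mrisr_volume")) test$data else test
  if (!all(dim(r) == dim(t))) stop("ssim: shapes differ")
  if (length(dim(r)) == 3L) {
    return(mean(vapply(seq_len(dim(r)[3]),
                       function(s) ssim_slice(r[, , s], t[, , s], peak), 0)))
  }
  ssim_slice(r, t, peak)
}

# ---- FSIM: phase congruency + gradient similarity ------------------------
# Frozen log-Gabor filter bank: 4 scales (min wavelength 6, multiplier 2,
# sigmaOnf 0.55), 4 orientations (angular sigma pi/4/1.2), Rayleigh noise
# threshold with k = 2.

fsim_freq_grids <- function(nr, nc) {
  fx <- if (nc %% 2) seq(-(nc - 1) / 2, (nc - 1) / 2) / (nc - 1)
        else seq(-nc / 2, nc / 2 - 1) / nc
  fy <- if (nr %% 2) seq(-(nr - 1) / 2, (nr - 1) / 2) / (nr - 1)
        else seq(-nr / 2, nr / 2 - 1) / nr
  # ifftshift
  fx <- fx[c(((floor(nc / 2)) + 1):nc, 1:(floor(nc / 2)))]
  fy <- fy[c(((floor(nr / 2)) + 1):nr, 1:(floor(nr / 2)))]
  X <- matrix(fx, nr, nc, byrow = TRUE)
  Y <- matrix(fy, nr, nc)
  radius <- sqrt(X^2 + Y^2)
  radius[1, 1] <- 1
  list(radius = radius, theta = atan2(-Y, X))
}

phase_congruency <- function(img, nscale = 4L, norient = 4L,
                             min_wavelength = 6, mult = 2, sigma_onf = 0.55,
                             k = 2) {
  d <- dim(img)
  gr <- fsim_freq_grids(d[1], d[2])
  radius <- gr$radius
  sintheta <- sin(gr$theta); costheta <- cos(gr$theta)
  lp <- 1 / (1 + (radius / 0.45)^30)  # butterworth lowpass, cutoff .45 n 15
  IM <- stats::fft(img)
  logGabor <- vector("list", nscale)
  for (s in seq_len(nscale)) {
    fo <- 1 / (min_wavelength * mult^(s - 1))
    lg <- exp(-(log(radius / fo))^2 / (2 * log(sigma_onf)^2)) * lp
    lg[1, 1] <- 0
    logGabor[[s]] <- lg
  }
  theta_sigma <- pi / norient / 1.2
  pc_sum <- matrix(0, d[1], d[2])
  for (o in seq_len(norient)) {
    angl <- (o - 1) * pi / norient
    ds <- sintheta * cos(angl) - costheta * sin(angl)
    dc <- costheta * cos(angl) + sintheta * sin(angl)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * theta_sigma^2))
    sumE <- matrix(0, d[1], d[2]); sumO <- matrix(0, d[1], d[2])
    sumAn <- matrix(0, d[1], d[2])
    tau <- 0
    for (s in seq_len(nscale)) {
      filt <- logGabor[[s]] * spread
      eo <- stats::fft(IM * filt, inverse = TRUE) / length(IM)
      E <- Re(eo); O <- Im(eo)
      An <- sqrt(E^2 + O^2)
      sumE <- sumE + E; sumO <- sumO + O; sumAn <- sumAn + An
      if (s == 1L) tau <- stats::median(An) / sqrt(log(4))
    }
    energy <- sqrt(sumE^2 + sumO^2)
    total_tau <- tau * (1 - (1 / mult)^nscale) / (1 - 1 / mult)
    noise_mean <- total_tau * sqrt(pi / 2)
    noise_sigma <- total_tau * sqrt((4 - pi) / 2)
    T0 <- noise_mean + k * noise_sigma
    pc_sum <- pc_sum + pmax(energy - T0, 0) / (sumAn + 1e-4)
  }
  pc_sum / norient
}

# Scharr gradient magnitude with symmetric padding
scharr_gradmag <- function(img) {
  kx <- matrix(c(3, 10, 3, 0, 0, 0, -3, -10, -3), 3, 3) / 16
  p <- pad_symmetric(img, 1L)
  d <- dim(img)
  gx <- matrix(0, d[1], d[2]); gy <- matrix(0, d[1], d[2])
  for (i in 1:3) for (j in 1:3) {
    blk <- p[(i):(i + d[1] - 1L), (j):(j + d[2] - 1L)]
    gx <- gx + kx[i, j] * blk
    gy <- gy + kx[j, i] * blk
  }
  sqrt(gx^2 + gy^2)
}

fsim_slice <- function(r, t) {
  # standard preprocessing: mild smoothing + decimation for large images
  f <- max(1L, round(min(dim(r)) / 256))
  if (f > 1L) {
    r <- decimate(gaussian_blur(r, f / 2), f)
    t <- decimate(gaussian_blur(t, f / 2), f)
  }
  pc1 <- phase_congruency(r)
  pc2 <- phase_congruency(t)
  g1 <- scharr_gradmag(r)
  g2 <- scharr_gradmag(t)
  T1 <- 0.85; T2 <- 160
  s_pc <- (2 * pc1 * pc2 + T1) / (pc1^2 + pc2^2 + T1)
  s_g <- (2 * g1 * g2 + T2) / (g1^2 + g2^2 + T2)
  pcm <- pmax(pc1, pc2)
  sum(s_pc * s_g * pcm) / max(sum(pcm), 1e-12)
}

#' Feature similarity index
#'
#' FSIM compares phase-congruency maps (computed from a frozen log-Gabor
#' filter bank: 4 scales, 4 orientations) and Scharr gradient-magnitude
#' maps, pooling the combined similarity with phase-congruency weighting.
#' Intensities are rescaled to the 0-255 convention using the reference
#' peak. 3D volumes are scored slice-wise and averaged. Identical inputs
#' score exactly 1; blur and detail loss lower the score.
#'
#' @inheritParams psnr
#' @return scalar in `(0, 1]`.
#' @export
fsim <- function(ref, test, peak = NULL) {
  if (is.null(peak)) peak <- if (inherits(ref, "mrisr_volume")) ref$peak else 255
  r <- if (inherits(ref, "mrisr_volume")) ref$data else ref
  t <- if (inherits(test, "mrisr_volume")) test$data else test
  if (!all(dim(r) == dim(t))) stop("fsim: shapes differ")
  r <- r * (255 / peak); t <- t * (255 / peak)
  if (length(dim(r)) == 3L) {
    return(mean(vapply(seq_len(dim(r)[3]),
                       function(s) fsim_slice(r[, , s], t[, , s]), 0)))
  }
  fsim_slice(r, t)
}

#' Full quality report
#'
#' @inheritParams psnr
#' @return list with `psnr`, `ssim`, `fsim`.
#' @export
quality_report <- function(ref, test, peak = NULL) {
  list(psnr = psnr(ref, test, peak), ssim = ssim(ref, test, peak),
       fsim = fsim(ref, test, peak))
}
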