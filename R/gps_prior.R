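#' Gradient profile sharpness (GPS)
#'
#' The GPS of an edge pixel is the ratio h/w of the height to the width of
#' the 1-D intensity profile traced through the pixel along its gradient
#' direction: h is the intensity difference between the two flanking extrema
#' of the profile and w their separation in pixels (clamped at 1). High h
#' means high contrast; high w means blur; so higher GPS means sharper
#' detail. Non-edge pixels carry GPS 0.
#'
#' @name gps
NULL

# Central-difference gradient (zero on the one-pixel border).
image_gradient <- function(img) {
  d <- dim(img)
  gr <- matrix(0, d[1], d[2])
  gc <- matrix(0, d[1], d[2])
  gr[2:(d[1] - 1), ] <- (img[3:d[1], ] - img[1:(d[1] - 2), ]) / 2
  gc[, 2:(d[2] - 1)] <- (img[, 3:d[2]] - img[, 1:(d[2] - 2)]) / 2
  list(gr = gr, gc = gc, mag = sqrt(gr^2 + gc^2))
}

# Bilinear sampling with border clamping; r, c are real-valued matrices.
bilinear_sample <- function(img, r, c) {
  d <- dim(img)
  r <- pmin(pmax(r, 1), d[1]); c <- pmin(pmax(c, 1), d[2])
  r0 <- pmin(floor(r), d[1] - 1L); c0 <- pmin(floor(c), d[2] - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(as.vector(r0), as.vector(c0))
  v00 <- img[i00]
  v10 <- img[cbind(as.vector(r0) + 1L, as.vector(c0))]
  v01 <- img[cbind(as.vector(r0), as.vector(c0) + 1L)]
  v11 <- img[cbind(as.vector(r0) + 1L, as.vector(c0) + 1L)]
  out <- v00 * (1 - as.vector(fr)) * (1 - as.vector(fc)) +
    v10 * as.vector(fr) * (1 - as.vector(fc)) +
    v01 * (1 - as.vector(fr)) * as.vector(fc) +
    v11 * as.vector(fr) * as.vector(fc)
  matrix(out, nrow = nrow(r))
}

# GPS values at the given pixel indices of img, tracing profiles along the
# local gradient direction. Returns h/w per pixel (0 for degenerate
# profiles). reach: half-length of the traced profile in pixels.
gps_at_pixels <- function(img, idx, reach = 8, step = 0.5) {
  g <- image_gradient(img)
  n <- length(idx)
  if (!n) return(numeric(0))
  rc <- arrayInd(idx, dim(img))
  mag <- g$mag[idx]
  dr <- ifelse(mag > 0, g$gr[idx] / mag, 0)
  dc <- ifelse(mag > 0, g$gc[idx] / mag, 0)
  ts <- seq(step, reach, by = step)
  nt <- length(ts)
  # profile rows: [-reach .. 0 .. reach], uphill towards +t
  Rp <- outer(dr, ts); Cp <- outer(dc, ts)
  r0 <- rc[, 1]; c0 <- rc[, 2]
  prof_plus <- bilinear_sample(img, r0 + Rp, c0 + Cp)
  prof_minus <- bilinear_sample(img, r0 - Rp, c0 - Cp)
  center <- img[idx]
  gps <- numeric(n)
  for (i in seq_len(n)) {
    if (mag[i] <= 0) next
    p_up <- c(center[i], prof_plus[i, ])
    p_dn <- c(center[i], prof_minus[i, ])
    rng <- max(p_up, p_dn) - min(p_up, p_dn)
    if (rng <= 0) next
    tol <- 0.01 * rng
    # walk uphill until the profile stops rising, downhill until it stops
    # falling; flanking extrema define h and w
    iu <- 1L
    while (iu <= nt && (p_up[iu + 1L] - p_up[iu]) >= tol) iu <- iu + 1L
    idn <- 1L
    while (idn <= nt && (p_dn[idn] - p_dn[idn + 1L]) >= tol) idn <- idn + 1L
    h <- p_up[iu] - p_dn[idn]
    w <- max((iu - 1L) * step + (idn - 1L) * step, 1)
    if (h > 0) gps[i] <- h / w
  }
  gps
}

#' Compute the GPS map of a 2D slice
#'
#' Edge pixels are those whose gradient magnitude exceeds `edge_threshold`
#' times the image's maximum gradient magnitude; for each, the 1-D profile
#' along the gradient direction is traced and GPS = h/w recorded. Scaling
#' the image intensities by c > 0 scales every GPS value by exactly c, and
#' blurring an edge can only lower its GPS.
#'
#' @param img numeric matrix or 2D [volume()].
#' @param edge_threshold fraction of the maximum gradient magnitude
#'   (default 0.1).
#' @return an object of class `mrisr_gps` with `values` (matrix, 0 off
#'   edges) and `edge_mask` (logical matrix).
#' @export
compute_gps_map <- function(img, edge_threshold = 0.1) {
  if (inherits(img, "mrisr_volume")) img <- img$data
  d <- dim(img)
  if (any(d < 9L)) stop("image must be at least 9 pixels per axis")
  g <- image_gradient(img)
  thr <- edge_threshold * max(g$mag)
  mask <- g$mag > thr & g$mag > 0
  idx <- which(mask)
  values <- matrix(0, d[1], d[2])
  if (length(idx)) values[idx] <- gps_at_pixels(img, idx)
  mask <- mask & values > 0  # degenerate profiles drop out of the edge set
  values[!mask] <- 0
  structure(list(values = values, edge_mask = mask), class = "mrisr_gps")
}

chi2_hist_distance <- function(a, b, bins = 64L) {
  rng <- range(c(a, b))
  if (diff(rng) <= 0) rng <- rng + c(-0.5, 0.5)
  br <- seq(rng[1], rng[2], length.out = bins + 1L)
  p <- tabulate(findInterval(a, br, all.inside = TRUE), bins)
  q <- tabulate(findInterval(b, br, all.inside = TRUE), bins)
  p <- p / sum(p); q <- q / sum(q)
  0.5 * sum((p - q)^2 / (p + q + 1e-12))
}

#' Estimate piecewise-linear GPS gains
#'
#' The GPS distribution of the available LR image stands in for that of the
#' unknown HR image, while upsampled-LR (UR) GPS values are systematically
#' deflated by interpolation blur. The nonzero UR GPS range is split into 4
#' equal-count (quantile) regions; for each region i the gain `beta_i`
#' minimizes the Chi-squared distance between the histogram of the matching
#' LR GPS quantile band and the histogram of `beta_i` times the region's UR
#' values. The search is a log-spaced grid on [0.25, 8] refined by
#' golden-section.
#'
#' @param eta_L GPS map of the LR image ([compute_gps_map]).
#' @param eta_U GPS map of the upsampled LR image.
#' @param bins histogram bin count (default 64).
#' @return an object of class `mrisr_gains` with `boundaries` (3 interior
#'   cut points on the UR GPS range) and `gains` (beta_1..beta_4).
#' @export
estimate_piecewise_gains <- function(eta_L, eta_U, bins = 64L) {
  vL <- eta_L$values[eta_L$edge_mask]
  vU <- eta_U$values[eta_U$edge_mask]
  if (!length(vL) || !length(vU)) stop("both GPS maps need at least 1 edge pixel")
  probs <- c(0.25, 0.5, 0.75)
  bU <- stats::quantile(vU, probs, names = FALSE)
  bL <- stats::quantile(vL, probs, names = FALSE)
  cutsU <- c(-Inf, bU, Inf)
  cutsL <- c(-Inf, bL, Inf)
  gains <- numeric(4)
  for (i in 1:4) {
    ui <- vU[vU > cutsU[i] & vU <= cutsU[i + 1]]
    li <- vL[vL > cutsL[i] & vL <= cutsL[i + 1]]
    if (!length(ui) || !length(li)) {
      warning("GPS region ", i, " has no edge pixels; gain defaults to 1")
      gains[i] <- 1
      next
    }
    grid <- 2^seq(-2, 3, by = 0.125)
    d <- vapply(grid, function(b) chi2_hist_distance(li, b * ui, bins), 0)
    j <- which.min(d)
    lo <- grid[max(j - 1L, 1L)]; hi <- grid[min(j + 1L, length(grid))]
    opt <- stats::optimize(function(b) chi2_hist_distance(li, b * ui, bins),
                           interval = c(lo, hi))
    gains[i] <- if (opt$objective <= d[j]) opt$minimum else grid[j]
  }
  structure(list(boundaries = bU, gains = gains), class = "mrisr_gains")
}

#' Predict HR GPS values from UR GPS values
#'
#' Multiplies every nonzero UR GPS value by the gain of its region; the edge
#' mask is unchanged.
#'
#' @param eta_U a `mrisr_gps` map of the upsampled LR image.
#' @param gains a `mrisr_gains` object.
#' @return a `mrisr_gps` map of predicted HR GPS values.
#' @export
predict_hr_gps <- function(eta_U, gains) {
  v <- eta_U$values
  idx <- which(eta_U$edge_mask)
  region <- findInterval(v[idx], gains$boundaries, left.open = TRUE) + 1L
  v[idx] <- v[idx] * gains$gains[region]
  structure(list(values = v, edge_mask = eta_U$edge_mask), class = "mrisr_gps")
}

# GPS discrepancy term at the target's edge pixels.
gps_term <- function(img, target_gps) {
  idx <- which(target_gps$edge_mask)
  if (!length(idx)) return(0)
  cur <- gps_at_pixels(img, idx)
  sum((cur - target_gps$values[idx])^2)
}

#' One GPS-regularization descent step
#'
#' Nudges the image so that its GPS values at the target's edge pixels move
#' towards the target: the (diffused) GPS deficit modulates an unsharp-mask
#' correction, scaled by `lam`, with step halving (up to 5 times) so that
#' the squared GPS discrepancy never increases; if no decrease is found the
#' input is returned unchanged. `lam = 0` is the identity.
#'
#' @param x_hat numeric matrix or 2D [volume()], the current HR estimate.
#' @param target_gps the target `mrisr_gps` map (predicted HR GPS).
#' @param lam regularization weight (default 0.001).
#' @return corrected image (same type as input).
#' @export
gps_regularize <- function(x_hat, target_gps, lam = 0.001) {
  if (lam < 0) stop("lam must be >= 0")
  was_vol <- inherits(x_hat, "mrisr_volume")
  vol <- as_volume(x_hat)
  x <- vol$data
  if (lam == 0) return(x_hat)
  idx <- which(target_gps$edge_mask)
  if (!length(idx)) return(x_hat)
  cur <- gps_at_pixels(x, idx)
  D <- matrix(0, nrow(x), ncol(x))
  D[idx] <- target_gps$values[idx] - cur
  Ds <- gaussian_blur(D, 1)
  base <- x - gaussian_blur(x, 1)
  term0 <- sum((cur - target_gps$values[idx])^2)
  s <- lam
  for (i in 0:5) {
    cand <- x + s * Ds * base
    if (gps_term(cand, target_gps) < term0) {
      vol$data <- cand
      return(if (was_vol) vol else cand)
    }
    s <- s / 2
  }
  x_hat
}
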