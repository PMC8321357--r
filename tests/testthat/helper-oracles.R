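# Independent brute-force oracles used across the suite. These deliberately
# re-derive results with plain loops and dense arithmetic, sharing no code
# with the implementation paths they check.

# dense separable Gaussian blur with symmetric padding, pixel by pixel
oracle_gauss_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3.5 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2)); w <- w / sum(w)
  d <- dim(img)
  reflect <- function(i, n) {
    while (i < 1L || i > n) {
      if (i < 1L) i <- 1L - i
      if (i > n) i <- 2L * n + 1L - i
    }
    i
  }
  tmp <- img
  for (a in seq_len(d[1])) for (b in seq_len(d[2])) {
    acc <- 0
    for (t in -r:r) acc <- acc + w[t + r + 1] * img[reflect(a + t, d[1]), b]
    tmp[a, b] <- acc
  }
  out <- tmp
  for (a in seq_len(d[1])) for (b in seq_len(d[2])) {
    acc <- 0
    for (t in -r:r) acc <- acc + w[t + r + 1] * tmp[a, reflect(b + t, d[2])]
    out[a, b] <- acc
  }
  out
}

# double-loop non-local means matching the documented weight definition
oracle_nlm <- function(img, sr, pr, h) {
  d <- dim(img)
  P <- sr + pr
  ri <- c(rev(seq_len(P)), seq_len(d[1]), d[1] - seq_len(P) + 1L)
  ci <- c(rev(seq_len(P)), seq_len(d[2]), d[2] - seq_len(P) + 1L)
  ipad <- img[ri, ci]
  g1 <- exp(-((-pr:pr)^2) / (2 * max(pr / 2, 0.5)^2)); g1 <- g1 / sum(g1)
  G <- outer(g1, g1)
  out <- img
  for (a in seq_len(d[1])) for (b in seq_len(d[2])) {
    pa <- a + P; pb <- b + P
    num <- 0; den <- 0; wmax <- 0
    for (da in -sr:sr) for (db in -sr:sr) {
      if (da == 0 && db == 0) next
      diff <- ipad[(pa + da - pr):(pa + da + pr), (pb + db - pr):(pb + db + pr)] -
              ipad[(pa - pr):(pa + pr), (pb - pr):(pb + pr)]
      d2 <- sum(G * diff^2)
      w <- exp(-d2 / h^2)
      num <- num + w * ipad[pa + da, pb + db]
      den <- den + w
      wmax <- max(wmax, w)
    }
    wmax <- max(wmax, 1e-12)
    out[a, b] <- (num + wmax * img[a, b]) / (den + wmax)
  }
  out
}

# per-window SSIM with explicit loops (valid windows, Gaussian 11x11)
oracle_ssim <- function(r, t, peak) {
  g1 <- exp(-((-5:5)^2) / (2 * 1.5^2)); g1 <- g1 / sum(g1)
  G <- outer(g1, g1)
  C1 <- (0.01 * peak)^2; C2 <- (0.03 * peak)^2
  d <- dim(r)
  vals <- c()
  for (a in 1:(d[1] - 10)) for (b in 1:(d[2] - 10)) {
    wr <- r[a:(a + 10), b:(b + 10)]
    wt <- t[a:(a + 10), b:(b + 10)]
    mur <- sum(G * wr); mut <- sum(G * wt)
    vr <- sum(G * wr^2) - mur^2
    vt <- sum(G * wt^2) - mut^2
    cv <- sum(G * wr * wt) - mur * mut
    vals <- c(vals, ((2 * mur * mut + C1) * (2 * cv + C2)) /
                ((mur^2 + mut^2 + C1) * (vr + vt + C2)))
  }
  mean(vals)
}

# interior mask of near-zero-gradient pixels, eroded away from edges
flat_interior_mask <- function(img, peak = 255) {
  g <- mrisr:::image_gradient(img)$mag
  (g <= 0.01 * peak) & (gaussian_blur((g > 0.01 * peak) * 1, 2) < 0.02)
}
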