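test_that("Gaussian noise has the percent-of-peak standard deviation", {
  v <- volume(matrix(100, 1000, 1000), peak = 255)
  expect_identical(add_gaussian_noise(v, noise_spec("gaussian", 0))$data, v$data)
  out <- add_gaussian_noise(v, noise_spec("gaussian", 0.02, seed = 9))
  resid <- out$data - v$data
  # 2% of 255 -> sigma 5.1, checked by Monte Carlo on 10^6 voxels
  expect_lt(abs(sd(resid) - 5.1) / 5.1, 0.01)
  expect_lt(abs(mean(resid)), 0.05)
  # determinism
  out2 <- add_gaussian_noise(v, noise_spec("gaussian", 0.02, seed = 9))
  expect_identical(out$data, out2$data)
  expect_error(noise_spec("gaussian", -0.1), ">= 0")
})

test_that("Rician noise matches the Rayleigh limit at zero signal", {
  v <- volume(matrix(0, 1000, 1000), peak = 255)
  out <- add_rician_noise(v, noise_spec("rician", 0.02, seed = 4))
  expect_true(all(out$data >= 0))
  target <- 5.1 * sqrt(pi / 2)
  expect_lt(abs(mean(out$data) - target) / target, 0.01)
})

test_that("Rician noise is near-Gaussian at high SNR", {
  sigma <- 5.1
  v <- volume(matrix(50 * sigma, 200, 200), peak = 255)
  out <- add_rician_noise(v, noise_spec("rician", 0.02, seed = 5))
  resid <- as.vector(out$data - v$data)
  expect_gt(shapiro.test(resid[seq(1, length(resid), by = 130)])$p.value, 0.001)
  expect_error(add_rician_noise(volume(matrix(-1, 4, 4)),
                                noise_spec("rician", 0.02)), "non-negative")
})

test_that("degrade reduces to identity and preserves constants", {
  v <- volume(matrix(runif(64), 8, 8))
  expect_equal(degrade(v, degradation_model(1, 0))$data, v$data)
  cst <- volume(matrix(42, 12, 12))
  out <- degrade(cst, degradation_model(2, 1))
  expect_equal(dim(out$data), c(6L, 6L))
  expect_equal(max(abs(out$data - 42)), 0, tolerance = 1e-10)
  expect_equal(out$spacing, c(2, 2))
  expect_error(degrade(volume(matrix(0, 3, 3)), degradation_model(4, 1)),
               "extent")
})

test_that("degrade equals the dense convolution-then-subsample oracle", {
  set.seed(11)
  img <- matrix(rnorm(32 * 32), 32, 32)
  model <- degradation_model(2, 1.3)
  got <- degrade(volume(img), model)$data
  ref <- oracle_gauss_blur(img, 1.3)[seq(1, 32, 2), seq(1, 32, 2)]
  expect_lt(max(abs(got - ref)), 1e-10)
})

test_that("degrade is linear in the image", {
  set.seed(2)
  x1 <- matrix(rnorm(24^2), 24, 24); x2 <- matrix(rnorm(24^2), 24, 24)
  m <- degradation_model(3, 0.8)
  lhs <- degrade(volume(2.5 * x1 - 1.2 * x2), m)$data
  rhs <- 2.5 * degrade(volume(x1), m)$data - 1.2 * degrade(volume(x2), m)$data
  expect_lt(max(abs(lhs - rhs)), 1e-10)
})

test_that("Gaussian noise commutes with constant offsets under matched seeds", {
  v <- volume(matrix(runif(400, 0, 200), 20, 20))
  sp <- noise_spec("gaussian", 0.03, seed = 21)
  a <- add_gaussian_noise(volume(v$data + 17), sp)$data - 17
  b <- add_gaussian_noise(v, sp)$data
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("phantoms are deterministic with controlled levels and edges", {
  p1 <- make_phantom(c(64, 64), seed = 5)
  p2 <- make_phantom(c(64, 64), seed = 5)
  expect_identical(p1$data, p2$data)
  # hard-edged two-level phantom has exactly 2 distinct values
  p <- make_phantom(c(64, 64), contrast_levels = 2, edge_blur_range = c(0, 0),
                    seed = 1)
  expect_equal(length(unique(as.vector(p$data))), 2L)
  # gradient fraction strictly between 1% and 50% across seeds
  for (s in 1:10) {
    ph <- make_phantom(c(96, 96), seed = s)
    frac <- mean(mrisr:::image_gradient(ph$data)$mag > 0.01 * ph$peak)
    expect_gt(frac, 0.01)
    expect_lt(frac, 0.5)
  }
  # 3D phantoms have per-slice structure
  p3 <- make_phantom(c(32, 32, 4), seed = 2)
  expect_equal(dim(p3$data), c(32L, 32L, 4L))
  expect_false(identical(p3$data[, , 1], p3$data[, , 2]))
})

test_that("labeled patch ensembles are deterministic and class-faithful", {
  a <- make_labeled_patches(n_flat = 50, n_edge = 50, seed = 3)
  b <- make_labeled_patches(n_flat = 50, n_edge = 50, seed = 3)
  expect_identical(a$ensemble$hf, b$ensemble$hf)
  expect_equal(table(a$truth)[["flat"]], 50)
  # edge patches carry far more HF energy than flat patches
  en <- colSums(a$ensemble$hf^2)
  expect_gt(median(en[a$truth == "edge"]), 5 * median(en[a$truth == "flat"]))
})
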