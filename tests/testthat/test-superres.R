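test_that("dictionaries are orthonormal and complete on training patches", {
  ph <- make_phantom(c(48, 48), seed = 1)
  dicts <- build_dictionaries(ph$data, scales = 1.0, k = 6)
  expect_gt(length(dicts), 1L)
  for (d in dicts) {
    expect_lt(max(abs(crossprod(d$atoms) - diag(25))), 1e-8)
  }
  ens <- extract_patches(ph$data, 5)
  j <- 100
  lab <- mrisr:::route_patches(dicts, ens$hf[, j, drop = FALSE])
  A <- dicts[[lab]]$atoms
  rec <- A %*% crossprod(A, ens$hf[, j])
  expect_lt(max(abs(rec - ens$hf[, j])), 1e-8)
  expect_error(build_dictionaries(matrix(0, 3, 3), scales = 0.5), "small|pool")
})

test_that("sparse coding thresholds coefficients as documented", {
  set.seed(4)
  ph <- make_phantom(c(40, 40), seed = 2)
  dicts <- build_dictionaries(ph$data, scales = 1.0, k = 4)
  x <- rnorm(25)
  a0 <- sparse_code(x, dicts[[1]], threshold = 0)
  expect_equal(as.vector(dicts[[1]]$atoms %*% a0), x, tolerance = 1e-10)
  abig <- sparse_code(x, dicts[[1]], threshold = max(abs(a0)) + 1)
  expect_equal(abig, rep(0, 25))
  # nnz is non-increasing in the threshold
  nnz <- vapply(seq(0, 3, by = 0.25),
                function(th) sum(sparse_code(x, dicts[[1]], th) != 0), 0L)
  expect_true(all(diff(nnz) <= 0))
})

test_that("NLM preserves constants, stays in range, matches brute force", {
  cst <- matrix(3.5, 12, 12)
  expect_equal(nlm_lowfreq(cst), cst, tolerance = 1e-12)
  set.seed(12)
  img <- matrix(runif(64, 0, 10), 8, 8)
  got <- nlm_lowfreq(img, search_radius = 2, patch_radius = 1, h = 4)
  ref <- oracle_nlm(img, 2, 1, 4)
  expect_lt(max(abs(got - ref)), 1e-8)
  expect_true(all(got >= min(img) - 1e-9 & got <= max(img) + 1e-9))
  # infinite filter strength tends to the uniform search-window mean
  flat_w <- nlm_lowfreq(img, search_radius = 2, patch_radius = 1, h = 1e6)
  ref_w <- oracle_nlm(img, 2, 1, 1e6)
  expect_lt(max(abs(flat_w - ref_w)), 1e-8)
  ctr <- flat_w[5, 5]
  win <- img[3:7, 3:7]
  expect_lt(abs(ctr - mean(win)), 1e-4)
})

test_that("back projection descends the data-fidelity residual", {
  set.seed(3)
  model <- degradation_model(2, 1)
  x_true <- make_phantom(c(32, 32), seed = 9)$data
  y <- degrade(volume(x_true), model)$data
  # fixed point: consistent estimate is unchanged
  expect_identical(back_project(x_true, y, model), x_true)
  # mismatched estimate: one call strictly reduces the residual
  x0 <- matrix(runif(32 * 32, 0, 255), 32, 32)
  r0 <- sum((y - degrade(volume(x0), model)$data)^2)
  x1 <- back_project(x0, y, model)
  r1 <- sum((y - degrade(volume(x1), model)$data)^2)
  expect_lt(r1, r0)
  expect_error(back_project(x0, y[1:10, 1:10], model), "shapes")
})

test_that("the degradation operator satisfies the adjoint identity", {
  set.seed(8)
  model <- degradation_model(2, 1.1)
  for (i in 1:5) {
    x <- matrix(rnorm(24 * 24), 24, 24)
    y <- matrix(rnorm(12 * 12), 12, 12)
    lhs <- sum(degrade(volume(x), model)$data * y)
    up <- mrisr:::decimate_adjoint(y, 2, c(24, 24))
    rhs <- sum(x * mrisr:::gaussian_blur_adjoint2(up, 1.1))
    expect_lt(abs(lhs - rhs), 1e-8)
  }
})

test_that("degenerate configuration reproduces the input exactly", {
  set.seed(2)
  y <- volume(matrix(runif(40 * 40, 0, 255), 40, 40))
  out <- super_resolve(y, sr_config(factor = 1, lam = 0, max_iter = 5,
                                    noise_aware = FALSE, seed = 1),
                       degradation_model(1, 0))
  expect_lt(max(abs(out$data - y$data)), 1e-6)
})

test_that("super-resolution is deterministic and improves on interpolation", {
  ph <- make_phantom(c(64, 64), seed = 3)
  model <- degradation_model(2, 1)
  y <- degrade(ph, model)
  cfg <- sr_config(factor = 2, max_iter = 4, seed = 1)
  hr1 <- super_resolve(y, cfg)
  hr2 <- super_resolve(y, cfg)
  expect_identical(hr1$data, hr2$data)
  expect_equal(dim(hr1$data), c(64L, 64L))
  expect_equal(hr1$spacing, y$spacing / 2)
  sp <- mrisr:::spline_upsample(y$data, 2)
  expect_gt(psnr(ph, hr1), psnr(ph$data, sp))
})

test_that("data-fidelity residual never increases across SR iterations", {
  ph <- make_phantom(c(48, 48), seed = 5)
  model <- degradation_model(2, 1)
  y <- degrade(ph, model)
  resid <- function(x) sum((y$data - degrade(volume(x), model)$data)^2)
  # run iterations manually through back_project on successive estimates
  x <- mrisr:::spline_upsample(y$data, 2)
  r_prev <- resid(x)
  for (i in 1:4) {
    x <- back_project(x, y$data, model)
    r <- resid(x)
    expect_lte(r, r_prev + 1e-9)
    r_prev <- r
  }
})

test_that("sr_config validates and carries the documented defaults", {
  cfg <- sr_config()
  expect_equal(cfg$max_iter, 320L)
  expect_equal(cfg$lam, 0.001)
  expect_equal(cfg$factor, 2L)
  expect_error(sr_config(factor = 0), "factor")
  expect_error(sr_config(eps = 0), "eps")
  expect_error(sr_config(lam = -1), "lam")
  expect_error(super_resolve(volume(matrix(0, 8, 8)), sr_config(factor = 2),
                             degradation_model(3, 1)), "match")
})
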