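test_that("extraction counts, order and bounds are as documented", {
  img <- matrix(seq_len(49), 7, 7)
  ens <- extract_patches(img, 5, 1)
  expect_equal(ncol(ens$hf), 9L)                 # (7-5+1)^2
  expect_equal(ens$locations[1, ], c(row = 0, col = 0))
  expect_true(all(ens$locations >= 0 & ens$locations <= 2))

  one <- extract_patches(matrix(1:25, 5, 5), 5)
  expect_equal(ncol(one$hf), 1L)
  expect_equal(one$hf[, 1] + one$lf_mean[1], as.vector(matrix(1:25, 5, 5)))
  expect_error(extract_patches(matrix(0, 4, 4), 5), "exceeds")
})

test_that("LF/HF split reconstructs exactly and HF sums to zero", {
  expect_equal(split_lf_hf(rep(7, 9)), list(lf = rep(7, 9), hf = rep(0, 9)))
  set.seed(1)
  for (i in 1:5) {
    x <- rnorm(25)
    s <- split_lf_hf(x)
    expect_lt(abs(sum(s$hf)), 1e-10)
    expect_equal(s$lf + s$hf, x, tolerance = 1e-12)
  }
})

test_that("extract then aggregate is the identity", {
  set.seed(4)
  img <- matrix(runif(19 * 23, 0, 255), 19, 23)
  for (stride in c(1L, 2L, 7L)) {
    # strides dividing extent - patch_size tile the image fully
    if ((19 - 5) %% stride == 0 && (23 - 5) %% stride == 0) {
      rec <- aggregate_patches(extract_patches(img, 5, stride))
      expect_lt(max(abs(rec - img)), 1e-10)
      expect_equal(attr(rec, "uncovered"), 0)
    }
  }
})

test_that("overlap averaging takes the mean of disagreeing patches", {
  img <- matrix(0, 5, 6)
  ens <- extract_patches(img, 5, 1)   # two patches, columns 0 and 1
  ens$hf[, 1] <- ens$hf[, 1]          # patch 1 stays 0
  ens$lf_mean <- c(0, 2)              # patch 2 disagrees by 2 everywhere
  rec <- aggregate_patches(ens)
  expect_equal(rec[3, 1], 0)          # covered only by patch 1
  expect_equal(rec[3, 6], 2)          # covered only by patch 2
  expect_equal(rec[3, 3], 1)          # overlap -> mean of 0 and 2
})

test_that("clustering recovers well-separated clouds and is reproducible", {
  set.seed(9)
  m <- 25
  c1 <- matrix(rnorm(m * 40, mean = 0, sd = 0.1), m)
  c2 <- matrix(rnorm(m * 40, mean = 6, sd = 0.1), m)
  hf <- cbind(c1, c2)
  ens <- mrisr:::new_patch_ensemble(hf, rep(0, 80),
                                    cbind(rep(0, 80), rep(0, 80)), 5L,
                                    c(5L, 5L))
  out <- cluster_patches(ens, k = 2)
  truth <- rep(0:1, each = 40)
  agree <- max(mean(out$labels == truth), mean(out$labels == 1 - truth))
  expect_equal(agree, 1)
  # k = 1 puts everything in label 0; same call twice gives identical labels
  expect_true(all(cluster_patches(ens, k = 1)$labels == 0))
  expect_identical(cluster_patches(ens, k = 2)$labels, out$labels)
  expect_error(cluster_patches(ens, k = 100), "exceed")
})

test_that("cluster labels are invariant to patch ordering", {
  set.seed(13)
  img <- matrix(runif(30 * 30, 0, 255), 30, 30)
  ens <- extract_patches(img, 5)
  out <- cluster_patches(ens, k = 6)
  perm <- sample(ncol(ens$hf))
  ens_p <- ens
  ens_p$hf <- ens$hf[, perm]
  ens_p$lf_mean <- ens$lf_mean[perm]
  ens_p$locations <- ens$locations[perm, ]
  out_p <- cluster_patches(ens_p, k = 6)
  expect_identical(out_p$labels, out$labels[perm])
})

test_that("cluster assignments agree with stats::kmeans on its own centers", {
  # cross-check: patches must sit nearest their assigned centroid, which is
  # exactly the fixed point stats::kmeans converges to
  set.seed(5)
  img <- matrix(runif(20 * 20, 0, 100), 20, 20)
  ens <- cluster_patches(extract_patches(img, 5), k = 4)
  C <- ens$centers
  d2 <- -2 * crossprod(ens$hf, C) + colSums(ens$hf^2)
  d2 <- sweep(d2, 2, colSums(C^2), `+`)
  expect_equal(max.col(-d2) - 1L, ens$labels)
  km <- suppressWarnings(stats::kmeans(t(ens$hf), centers = t(C),
                                       iter.max = 1, algorithm = "Lloyd"))
  expect_equal(unname(km$cluster) - 1L, ens$labels)
})
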