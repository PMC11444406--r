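test_that("SLIC produces a connected partition with at most K segments", {
  img <- generate_phantom(phantom_spec(seed = 3))$image
  sp <- slic_oversegment(img, 64)
  expect_s3_class(sp, "superpixel_map")
  expect_lte(sp$n_segments, 64)
  expect_identical(sort(unique(as.vector(sp$labels))),
                   0:(sp$n_segments - 1))
  expect_identical(sum(tabulate(as.vector(sp$labels) + 1L)), length(img))
  for (l in 0:(sp$n_segments - 1)) {
    comp <- EBImage::bwlabel(sp$labels == l)
    expect_equal(max(comp), 1)           # 4-connected
  }
})

test_that("SLIC trivial and degenerate cases", {
  img <- matrix(stats::runif(64), 8)
  expect_identical(unique(as.vector(slic_oversegment(img, 1)$labels)), 0L)
  expect_error(slic_oversegment(img, 100), "invalid argument")
  # constant image at high compactness degenerates toward grid tiles
  spc <- slic_oversegment(matrix(0.5, 64, 64), 16, compactness = 1000)
  fill <- vapply(0:(spc$n_segments - 1), function(l) {
    px <- which(spc$labels == l, arr.ind = TRUE)
    nrow(px) / ((diff(range(px[, 1])) + 1) * (diff(range(px[, 2])) + 1))
  }, numeric(1))
  expect_gt(min(fill), 0.6)
})

test_that("SLIC is invariant to global intensity shifts", {
  img <- generate_phantom(phantom_spec(seed = 5))$image
  expect_identical(slic_oversegment(img, 32)$labels,
                   slic_oversegment(img + 7, 32)$labels)
})

test_that("superpixel mean pooling matches a per-label loop oracle", {
  withr::with_seed(2, {
    for (rep in 1:20) {
      f <- array(stats::rnorm(8 * 8 * 3), c(8, 8, 3))
      img <- matrix(stats::runif(64), 8)
      sp <- slic_oversegment(img, 4)
      pooled <- unclass(superpixel_pool(f, sp))
      for (l in 0:(sp$n_segments - 1)) {
        sel <- sp$labels == l
        for (ch in 1:3) {
          expect_equal(pooled[l + 1, ch], mean(f[, , ch][sel]),
                       tolerance = 1e-6)
        }
      }
    }
  })
})

test_that("single-pixel superpixels pool to the feature map itself", {
  f <- array(stats::rnorm(4 * 4 * 2), c(4, 4, 2))
  sp <- structure(list(labels = matrix(0:15, 4), n_segments = 16L,
                       compactness = 10), class = "superpixel_map")
  pooled <- unclass(superpixel_pool(f, sp))
  expect_equal(pooled, cbind(as.vector(f[, , 1]), as.vector(f[, , 2])),
               ignore_attr = TRUE)
})

test_that("pool and unpool satisfy the projection identities", {
  img <- generate_phantom(phantom_spec(height = 32, width = 32,
                                       radius_range = c(4, 7),
                                       seed = 4))$image
  sp <- slic_oversegment(img, 16)
  f <- array(stats::rnorm(32 * 32 * 3), c(32, 32, 3))
  P <- superpixel_pool(f, sp)
  U <- shape_shared_unpool(P, sp)
  # pooling a piecewise-constant map returns its constants (to the last ulp
  # of re-averaging identical values)
  expect_equal(unclass(superpixel_pool(U, sp)), unclass(P),
               tolerance = 1e-14)
  # unpool(pool(.)) is idempotent
  U2 <- shape_shared_unpool(superpixel_pool(U, sp), sp)
  expect_equal(U, U2, tolerance = 1e-14)
  # two-superpixel toy: exact piecewise-constant reconstruction
  toy <- structure(list(labels = cbind(matrix(0L, 4, 2), matrix(1L, 4, 2)),
                        n_segments = 2L, compactness = 10),
                   class = "superpixel_map")
  rec <- shape_shared_unpool(matrix(c(1, -2), 2, 1), toy)
  expect_equal(rec[, , 1], cbind(matrix(1, 4, 2), matrix(-2, 4, 2)))
  expect_error(shape_shared_unpool(matrix(1, 1, 1), toy), "inconsistent")
})

test_that("constant-feature pooling broadcasts the constant", {
  img <- matrix(stats::runif(64), 8)
  sp <- slic_oversegment(img, 4)
  f <- array(3.25, c(8, 8, 2))
  expect_true(all(abs(unclass(superpixel_pool(f, sp)) - 3.25) < 1e-12))
})

test_that("the shape-guided block smooths within superpixels residually", {
  img <- generate_phantom(phantom_spec(height = 32, width = 32,
                                       radius_range = c(4, 7),
                                       seed = 6))$image
  # constant features double under the residual combination
  fc <- array(1.5, c(32, 32, 2))
  expect_equal(shape_guided_block(fc, img, K = 8), fc * 2)
  # piecewise-constant features have zero within-superpixel variance after SGB
  sp <- slic_oversegment(img, 8)
  fpc <- array(shape_shared_unpool(superpixel_pool(
    array(stats::rnorm(32 * 32), c(32, 32, 1)), sp), sp), c(32, 32, 1))
  out <- shape_guided_block(fpc, img, K = 8)
  wv <- vapply(0:(sp$n_segments - 1), function(l)
    stats::var(out[, , 1][sp$labels == l]), numeric(1))
  expect_lt(max(wv, na.rm = TRUE), 1e-18)
  # white noise: within-superpixel variance strictly decreases
  fn <- array(stats::rnorm(32 * 32), c(32, 32, 1))
  outn <- shape_guided_block(fn, img, K = 2)
  spn <- slic_oversegment(img, 2)
  for (l in 0:(spn$n_segments - 1)) {
    sel <- spn$labels == l
    expect_lt(stats::var((outn[, , 1] / 2)[sel]), stats::var(fn[, , 1][sel]))
  }
  # adding a constant to the guidance image changes nothing
  expect_equal(shape_guided_block(fn, img + 3, K = 8),
               shape_guided_block(fn, img, K = 8))
})

test_that("the shared classification layer is a per-pixel linear map", {
  f0 <- array(stats::rnorm(6 * 6 * 3), c(6, 6, 3))
  z <- shared_classification_layer(f0, list(w = numeric(3), b = 0))
  expect_true(all(z == 0))
  expect_true(all(stats::plogis(z) == 0.5))
  f1 <- array(stats::rnorm(36), c(6, 6, 1))
  expect_equal(shared_classification_layer(f1, list(w = 1, b = 0)),
               f1[, , 1])
  # F = 2 toy with weights (1, -1), bias 0.5, on printed 2x2 values
  fa <- array(c(0.2, 0.4, 0.6, 0.8,  0.1, 0.3, 0.5, 0.7), c(2, 2, 2))
  za <- shared_classification_layer(fa, list(w = c(1, -1), b = 0.5))
  expect_equal(za, matrix(c(0.2 - 0.1, 0.4 - 0.3, 0.6 - 0.5, 0.8 - 0.7),
                          2, 2) + 0.5)
  expect_error(shared_classification_layer(fa, list(w = 1, b = 0)),
               "invalid argument")
})
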