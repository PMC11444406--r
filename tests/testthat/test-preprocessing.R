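test_that("resize reaches the target shape and respects trivial cases", {
  img <- matrix(stats::rnorm(512 * 512), 512)
  out <- resize_image(img, c(256, 256))
  expect_identical(dim(out), c(256L, 256L))
  # identity at equal size
  small <- matrix(stats::rnorm(64), 8)
  expect_identical(resize_image(small, c(8, 8)), small)
  # a constant image stays constant under interpolation
  const <- matrix(2.5, 32, 32)
  expect_equal(unique(as.vector(resize_image(const, c(16, 16)))), 2.5)
  expect_error(resize_image(img, c(0, 10)), "invalid argument")
})

test_that("nearest-neighbour resize keeps masks binary", {
  m <- random_blob_mask(32, seed = 2)
  out <- resize_image(m, c(17, 23), method = "nearest")
  expect_true(all(out %in% c(0, 1)))
})

test_that("z-normalisation has population mean 0 / SD 1 and is idempotent", {
  img <- matrix(stats::rnorm(100, mean = 7, sd = 3), 10)
  z <- zscore_normalize(img)
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-6)
  expect_equal(zscore_normalize(z), z, tolerance = 1e-8)
  # hand-computed two-pixel case, population SD = 1
  expect_equal(as.vector(zscore_normalize(matrix(c(0, 2), 1))), c(-1, 1))
  expect_error(zscore_normalize(matrix(1, 4, 4)), "degenerate")
})

test_that("outlier clipping clamps exactly and passes interior values", {
  x <- matrix(c(-6, -1, 0, 6), 2)
  expect_equal(as.vector(clip_outliers(x, 5)), c(-5, -1, 0, 5))
  inside <- matrix(stats::runif(64, -4, 4), 8)
  expect_identical(clip_outliers(inside, 5), inside)
  y <- matrix(stats::rnorm(100, sd = 3), 10)
  expect_equal(max(clip_outliers(y, 5)), min(5, max(y)))
  expect_error(clip_outliers(x, 0), "invalid argument")
})

test_that("unit rescale is the affine map onto [0, 1]", {
  expect_equal(as.vector(rescale_unit(matrix(c(-5, 0, 5), 1))), c(0, 0.5, 1))
  x <- matrix(stats::rnorm(100), 10)
  r <- rescale_unit(x)
  expect_equal(range(r), c(0, 1))
  bin <- matrix(c(0, 1, 1, 0), 2)
  expect_identical(rescale_unit(bin), bin)
  expect_error(rescale_unit(matrix(3, 2, 2)), "degenerate")
})

test_that("the full chain lands in [0,1] at the target size", {
  img <- matrix(stats::rnorm(120 * 90, 50, 12), 120)
  img[1, 1] <- 500   # extreme outlier
  out <- preprocess_image(img, preproc_config(target_size = c(256, 256)))
  expect_identical(dim(out), c(256L, 256L))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("elastic deformation is seeded, shared, and mask-preserving", {
  ph <- generate_phantom(phantom_spec(height = 32, width = 32,
                                      radius_range = c(4, 7), seed = 3))
  # alpha = 0 is the identity
  id <- elastic_deform(ph$image, ph$mask, alpha = 0)
  expect_identical(id$image, ph$image)
  # determinism under a seed
  a <- elastic_deform(ph$image, ph$mask, alpha = 6, sigma = 3, seed = 4)
  b <- elastic_deform(ph$image, ph$mask, alpha = 6, sigma = 3, seed = 4)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_false(identical(a$image, ph$image))
  expect_true(all(a$mask %in% c(0, 1)))
  expect_error(elastic_deform(ph$image, ph$mask[1:10, ]), "invalid argument")
})

test_that("smooth displacement fields roughly preserve mask area", {
  ph <- generate_phantom(phantom_spec(height = 64, width = 64,
                                      radius_range = c(8, 10), seed = 5))
  a0 <- sum(ph$mask)
  rel <- vapply(1:10, function(s) {
    d <- elastic_deform(ph$image, ph$mask, alpha = 10, sigma = 4, seed = s)
    abs(sum(d$mask) - a0) / a0
  }, numeric(1))
  expect_lt(max(rel), 0.15)
})
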