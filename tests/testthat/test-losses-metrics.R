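mk <- function(v, n = 4) matrix(v, n, n)

test_that("Dice identities and the hand-counted case", {
  g <- mk(0); g[1:2, 1] <- 1
  expect_equal(dice_coefficient(g, g), 1)
  p <- mk(0); p[3:4, 4] <- 1
  expect_equal(dice_coefficient(p, g), 0)
  # |P| = 2, |G| = 4, overlap 2
  g2 <- mk(0); g2[1:4, 1] <- 1
  p2 <- mk(0); p2[1:2, 1] <- 1
  expect_equal(dice_coefficient(p2, g2), 2 * 2 / (2 + 4))
  expect_equal(dice_loss(p2, g2), 1 - 2 / 3)
  expect_equal(dice_loss(g, g), 0)
  expect_equal(dice_loss(p, g), 1)
  expect_error(dice_coefficient(p, matrix(0, 3, 3)), "shape mismatch")
})

test_that("BCE closed forms", {
  y <- mk(c(0, 1))
  expect_equal(bce_loss(y, mk(0.5)), log(2), tolerance = 1e-12)
  # perfect prediction after clamping
  expect_lt(bce_loss(y, y), 1e-6)
  # single pixel y = 1, p = 0.8
  expect_equal(bce_loss(matrix(1, 1, 1), matrix(0.8, 1, 1)), -log(0.8))
  expect_gt(bce_loss(y, mk(0.9)), 0)
})

test_that("combined loss is the convex combination of its components", {
  y <- mk(c(0, 1, 1, 0)); p <- mk(stats::runif(16, 0.05, 0.95))
  for (a in c(0, 0.25, 0.5, 0.75, 1)) {
    cfg <- loss_config(alpha = a)
    d <- dice_loss(p, y, epsilon = cfg$epsilon)
    b <- bce_loss(y, p, cfg$prob_clip)
    expect_equal(combined_loss(y, p, cfg), a * d + (1 - a) * b)
    expect_gte(combined_loss(y, p, cfg), min(d, b) - 1e-12)
    expect_lte(combined_loss(y, p, cfg), max(d, b) + 1e-12)
  }
})

test_that("focal loss reduces to BCE at gamma 0 and down-weights easy pixels", {
  y <- mk(c(0, 1)); p <- mk(stats::runif(16, 0.1, 0.9))
  expect_equal(focal_loss(y, p, gamma = 0), bce_loss(y, p))
  # p = 0.5, y = 1, gamma = 2 -> 0.25 * ln 2 per pixel
  expect_equal(focal_loss(matrix(1, 1, 1), matrix(0.5, 1, 1), gamma = 2),
               0.25 * log(2))
  easy <- focal_loss(matrix(1, 1, 1), matrix(0.99, 1, 1), gamma = 2)
  expect_lt(easy, 1e-3 * bce_loss(matrix(1, 1, 1), matrix(0.5, 1, 1)))
})

test_that("mIoU hand counts and conventions", {
  g <- mk(0); g[1:4, 1] <- 1
  p <- mk(0); p[1:2, 1] <- 1
  expect_equal(class_iou(p, g), 0.5)
  expect_equal(miou(g, g), 1)
  z <- mk(0)
  expect_equal(class_iou(z, z), 1)   # empty class scores 1 by convention
})

test_that("pixel accuracy counts agreements", {
  g <- mk(c(0, 1))
  expect_equal(pixel_accuracy(g, g), 1)
  expect_equal(pixel_accuracy(1 - g, g), 0)
  p <- matrix(c(1, 1, 0, 0), 2); y <- matrix(c(1, 1, 0, 1), 2)
  expect_equal(pixel_accuracy(p, y), 0.75)
})

test_that("Dice and IoU obey Dice = 2 IoU / (1 + IoU) on random masks", {
  withr::with_seed(9, {
    for (i in 1:100) {
      a <- matrix(stats::runif(64) < 0.4, 8) * 1
      b <- matrix(stats::runif(64) < 0.4, 8) * 1
      iou <- class_iou(a, b)
      expect_equal(dice_coefficient(a, b), 2 * iou / (1 + iou),
                   tolerance = 1e-9)
    }
  })
})

test_that("hd95 basics: identity, translation, spacing, symmetry", {
  sq <- matrix(0, 32, 32); sq[10:19, 10:19] <- 1
  expect_equal(hd95(sq, sq), 0)
  tr <- matrix(0, 32, 32); tr[13:22, 10:19] <- 1   # translated by 3 rows
  expect_equal(hd95(sq, tr), 3)
  expect_equal(hd95(sq, tr, spacing = 0.5), 1.5)
  a <- random_blob_mask(32, 1); b <- random_blob_mask(32, 2)
  expect_equal(hd95(a, b), hd95(b, a))
  expect_error(hd95(sq, matrix(0, 32, 32)), "undefined metric")
})

test_that("hd95 never exceeds the exact Hausdorff distance", {
  withr::with_seed(4, {
    for (i in 1:20) {
      a <- random_blob_mask(24, seed = i)
      b <- random_blob_mask(24, seed = i + 100)
      expect_lte(hd95(a, b), hd95_oracle(a, b, q = 1) + 1e-9)
    }
  })
})
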