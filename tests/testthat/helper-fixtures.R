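# Shared fixtures: all inputs are generated in code at test time.

# Small standardised phantom pairs for pipeline-level tests.
phantom_pairs <- function(n, size = 32, seed = 1, contrast = 3,
                          radius = c(3, 6)) {
  ds <- generate_dataset(phantom_spec(height = size, width = size,
                                      radius_range = radius,
                                      contrast = contrast, seed = seed),
                         n = n, seed = seed)
  lapply(ds$phantoms, function(p)
    list(image = rescale_unit(clip_outliers(zscore_normalize(p$image), 5)),
         mask = p$mask))
}

# A quick random binary blob mask (always non-empty).
random_blob_mask <- function(size = 32, seed = 1, q = 0.8) {
  withr::with_seed(seed, {
    f <- matrix(stats::rnorm(size^2), size)
    f <- as.matrix(EBImage::gblur(f, sigma = 3, radius = 13))
    m <- (f >= stats::quantile(f, q)) * 1
    if (sum(m) == 0) m[size %/% 2, size %/% 2] <- 1
    m
  })
}

# One small trained model shared by the inference/QA tests (trained once per
# test run on 32x32 phantoms; a desk-scale stand-in for a converged model).
.fixture_env <- new.env()
toy_trained_model <- function() {
  if (is.null(.fixture_env$toy)) {
    ds <- generate_dataset(phantom_spec(height = 32, width = 32,
                                        radius_range = c(3, 6), contrast = 3,
                                        seed = 11), n = 40, seed = 11)
    fit <- ncaseg(ds,
                  model = model_config(steps_coarse = 6, steps_fine = 6,
                                       sgb_sp_area = 32, seed = 11),
                  train = train_config(learning_rate = 0.02, max_epochs = 120,
                                       early_stop_patience = 1000,
                                       val_every = 30, val_max = 4,
                                       batch_size = 2, duplication = 2,
                                       seed = 11))
    .fixture_env$toy <- fit
  }
  .fixture_env$toy
}

# Brute-force HD95 oracle: all-pairs boundary distances, independent of the
# package's distance-transform implementation.
hd95_oracle <- function(a, b, q = 0.95) {
  boundary_pts <- function(m) {
    h <- nrow(m); w <- ncol(m)
    pts <- NULL
    for (i in seq_len(h)) for (j in seq_len(w)) {
      if (m[i, j] != 0) {
        nb <- c(if (i > 1) m[i - 1, j] else 0, if (i < h) m[i + 1, j] else 0,
                if (j > 1) m[i, j - 1] else 0, if (j < w) m[i, j + 1] else 0)
        if (any(nb == 0) || i == 1 || i == h || j == 1 || j == w)
          pts <- rbind(pts, c(i, j))
      }
    }
    pts
  }
  pa <- boundary_pts(a); pb <- boundary_pts(b)
  D <- sqrt(outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2)
  max(stats::quantile(apply(D, 1, min), q, names = FALSE),
      stats::quantile(apply(D, 2, min), q, names = FALSE))
}
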