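test_that("pseudo-ensemble averages stochastic runs", {
  fit <- toy_trained_model()
  img <- phantom_pairs(1, size = 32, seed = 31)[[1]]$image
  ens <- pseudo_ensemble(fit, img, n_e = 4, seed = 2, preprocess = FALSE)
  expect_identical(dim(ens$per_run_probs), c(4L, 32L, 32L))
  expect_equal(ens$mean_prob, apply(ens$per_run_probs, c(2, 3), mean))
  expect_true(all(ens$mean_prob >= 0 & ens$mean_prob <= 1))
  one <- pseudo_ensemble(fit, img, n_e = 1, seed = 2, preprocess = FALSE)
  expect_equal(one$mean_prob, one$per_run_probs[1, , ])
  expect_error(pseudo_ensemble(fit, img, n_e = 0), "invalid argument")
})

test_that("a deterministic model yields identical runs and zero variance", {
  fit <- toy_trained_model()
  m <- fit$model
  m$coarse$fire_rate <- 1
  m$fine$fire_rate <- 1
  img <- phantom_pairs(1, size = 32, seed = 32)[[1]]$image
  ens <- pseudo_ensemble(m, img, n_e = 3, seed = 1, preprocess = FALSE)
  expect_equal(max(ens$pixel_variance), 0)
  expect_equal(ens$per_run_probs[1, , ], ens$per_run_probs[3, , ])
  expect_equal(nqm(ens)$value, 0)
})

test_that("nqm matches the hand-computed population-SD case", {
  runs <- array(c(0.4, 0.6), c(2, 1, 1))
  q <- nqm(runs)
  expect_equal(q$value, 0.1 / 0.5)
  expect_equal(q$per_pixel_sd[1, 1], 0.1)
  expect_identical(q$n_runs, 2L)
  expect_error(nqm(array(1, c(1, 2, 2))), "invalid argument")
})

test_that("nqm is scale-invariant and monotone in inter-run noise", {
  withr::with_seed(5, {
    base <- array(stats::runif(6 * 8 * 8, 0.2, 0.8), c(6, 8, 8))
    expect_equal(nqm(base * 0.37)$value, nqm(base)$value)
    # runs that agree perfectly, then increasing i.i.d. inter-run noise
    agree <- array(rep(stats::runif(64, 0.3, 0.7), each = 6), c(6, 8, 8))
    expect_equal(nqm(agree)$value, 0)
    vals <- vapply(c(0.01, 0.05, 0.15), function(s) {
      noisy <- agree + array(stats::rnorm(length(agree), sd = s), dim(agree))
      nqm(noisy)$value
    }, numeric(1))
    expect_true(all(diff(c(0, vals)) > 0))
  })
  # identically-zero mean prediction is undefined, reported as missing
  expect_true(is.na(nqm(array(0, c(3, 4, 4)))$value))
})

test_that("ensemble-mean variability shrinks roughly as 1/sqrt(n_e)", {
  fit <- toy_trained_model()
  img <- phantom_pairs(1, size = 32, seed = 33)[[1]]$image
  # measure at the pixels where the stochastic output actually varies
  # (lesion boundary); background probabilities are pinned near 0
  pilot <- pseudo_ensemble(fit, img, n_e = 8, seed = 1, preprocess = FALSE)
  px <- order(pilot$pixel_variance, decreasing = TRUE)[1:40]
  # 40 repeats keep the sd-ratio estimate well away from its sampling noise
  single <- vapply(1:40, function(i)
    mean(forward_full(fit$model, img, seed = 200 + i)[px]), numeric(1))
  ens16 <- vapply(1:40, function(i)
    mean(pseudo_ensemble(fit, img, n_e = 16, seed = 400 + i,
                         preprocess = FALSE)$mean_prob[px]), numeric(1))
  expect_lt(stats::sd(ens16), stats::sd(single) / 3)
})

test_that("qa_report covers every image and flags only high NQM", {
  fit <- toy_trained_model()
  imgs <- lapply(phantom_pairs(3, size = 32, seed = 34), `[[`, "image")
  rep <- qa_report(fit, imgs, n_e = 4, seed = 9)
  expect_identical(nrow(rep), 3L)
  expect_true(all(c("id", "nqm", "ensemble_dice", "flagged") %in% names(rep)))
  expect_true(all(rep$nqm >= 0, na.rm = TRUE))
  # deterministic model: all NQM zero, nothing flagged
  m <- fit$model
  m$coarse$fire_rate <- 1; m$fine$fire_rate <- 1
  rep0 <- qa_report(m, imgs, n_e = 3, seed = 9)
  expect_true(all(rep0$nqm == 0))
  expect_false(any(rep0$flagged))
})
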