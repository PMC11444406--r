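#' Pseudo-ensemble inference
#'
#' Runs the model `n_e` times on the identical input with independent
#' stochastic cell firing and averages the probability maps. The ensemble
#' mean is the recommended prediction; the spread across runs feeds the
#' quality metric [nqm()].
#'
#' @param model An `ncaseg_model` or fitted [ncaseg()] object.
#' @param image Input image matrix (or `phantom`).
#' @param n_e Ensemble size (>= 1); default 10.
#' @param seed Optional seed.
#' @param preprocess Standardise the input first; default `TRUE`.
#' @return Object of class `ensemble_result`: list with `mean_prob` (H x W),
#'   `per_run_probs` (array `n_e x H x W`), `n_e`, and `pixel_variance`
#'   (population variance across runs, H x W).
#' @export
pseudo_ensemble <- function(model, image, n_e = 10, seed = NULL,
                            preprocess = TRUE) {
  if (n_e < 1) stopf("invalid argument: n_e must be >= 1")
  if (inherits(model, "ncaseg")) model <- model$model
  if (inherits(image, "phantom")) image <- image$image
  if (preprocess) image <- rescale_unit(clip_outliers(zscore_normalize(image), 5))
  n_e <- as.integer(n_e)
  runs <- with_seed(seed, lapply(seq_len(n_e), function(i)
    forward_batch(model, list(image))[[1]]))
  arr <- array(unlist(runs), c(nrow(runs[[1]]), ncol(runs[[1]]), n_e))
  arr <- aperm(arr, c(3, 1, 2))
  mu <- apply(arr, c(2, 3), mean)
  v <- apply(arr, c(2, 3), function(x) mean((x - mean(x))^2))
  structure(list(mean_prob = mu, per_run_probs = arr, n_e = n_e,
                 pixel_variance = v), class = "ensemble_result")
}

#' NCA quality metric: normalised inter-run deviation
#'
#' For `n` stochastic runs with per-pixel values `v_i`, the per-pixel
#' population deviation is `SD = sqrt(sum((v_i - mu)^2) / n)` and the score
#' is `sum(SD) / sum(mu)` over pixels — the deviation mass normalised by the
#' predicted-foreground mass. It is zero exactly when all runs agree, grows
#' with inter-run disagreement, and is invariant to rescaling all
#' probabilities by a positive constant. Computed on probabilities by
#' default; set `binarize` to use thresholded masks instead.
#'
#' @param per_run_probs Array `(n, H, W)` of per-run probability maps, or an
#'   `ensemble_result`.
#' @param binarize Optional threshold in (0, 1); when given, runs are
#'   binarised before the computation.
#' @return Object of class `nqm_score`: list with `value`, `n_runs` and
#'   `per_pixel_sd`. The value is `NA` (undefined) when the mean prediction
#'   is identically zero.
#' @export
nqm <- function(per_run_probs, binarize = NULL) {
  if (inherits(per_run_probs, "ensemble_result"))
    per_run_probs <- per_run_probs$per_run_probs
  d <- dim(per_run_probs)
  if (length(d) != 3 || d[1] < 2)
    stopf("invalid argument: need an (n >= 2, H, W) array of runs")
  if (!is.null(binarize)) per_run_probs <- (per_run_probs >= binarize) * 1
  mu <- apply(per_run_probs, c(2, 3), mean)
  sd_p <- sqrt(apply(per_run_probs, c(2, 3),
                     function(x) mean((x - mean(x))^2)))
  denom <- sum(mu)
  value <- if (denom == 0) NA_real_ else sum(sd_p) / denom
  structure(list(value = value, n_runs = d[1], per_pixel_sd = sd_p),
            class = "nqm_score")
}

#' @export
print.nqm_score <- function(x, ...) {
  cat(sprintf("<nqm: %.4f over %d runs>\n", x$value, x$n_runs))
  invisible(x)
}

#' Quality-assurance report over a set of images
#'
#' Runs pseudo-ensemble inference on every image and reports the NQM plus
#' ensemble agreement statistics (mean Dice of each run's binarised mask
#' against the binarised ensemble mean). Images whose NQM exceeds
#' `flag_threshold` are flagged for review.
#'
#' @param model An `ncaseg_model` or fitted [ncaseg()] object.
#' @param images List of image matrices (or `phantom`s), or a
#'   `phantom_dataset`.
#' @param n_e Ensemble size; default 10.
#' @param flag_threshold NQM level above which an image is flagged;
#'   default 0.5.
#' @param seed Optional seed.
#' @return Data frame with one row per image: `id`, `nqm`,
#'   `ensemble_dice` (mean run-vs-mean Dice), `flagged`.
#' @export
qa_report <- function(model, images, n_e = 10, flag_threshold = 0.5,
                      seed = NULL) {
  if (inherits(images, "phantom_dataset")) images <- images$phantoms
  if (is.matrix(images) || inherits(images, "phantom")) images <- list(images)
  if (inherits(model, "ncaseg")) model <- model$model
  thr <- model$config$threshold
  with_seed(seed, {
    rows <- lapply(seq_along(images), function(i) {
      ens <- pseudo_ensemble(model, images[[i]], n_e)
      q <- nqm(ens)
      mmask <- (ens$mean_prob >= thr) * 1
      run_dice <- vapply(seq_len(ens$n_e), function(r)
        dice_coefficient((ens$per_run_probs[r, , ] >= thr) * 1, mmask),
        numeric(1))
      data.frame(id = i, nqm = q$value, ensemble_dice = mean(run_dice),
                 flagged = !is.na(q$value) && q$value > flag_threshold)
    })
    do.call(rbind, rows)
  })
}
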