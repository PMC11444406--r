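#' @export
print.ncaseg <- function(x, ...) {
  cfg <- x$config$model
  cat("Multi-scale shape-guided NCA segmenter\n")
  cat(sprintf("  scales: %d (factor %d), coarse k=7->3, fine k=3%s\n",
              cfg$n_levels + 1, cfg$d,
              if (cfg$use_sgb) ", shape-guided block" else ""))
  cat(sprintf("  channels: 1 image + 1 logit + %d hidden; fire rate %.2f\n",
              cfg$n_hidden, cfg$fire_rate))
  cat(sprintf("  trained %d epochs (best validation at epoch %d)\n",
              nrow(x$history), x$best_epoch))
  h <- x$history[nrow(x$history), ]
  cat(sprintf("  final train loss %.4f, train Dice %.3f\n",
              h$train_loss, h$train_dice))
  vl <- x$history$val_loss[!is.na(x$history$val_loss)]
  if (length(vl)) cat(sprintf("  best validation loss %.4f\n", min(vl)))
  invisible(x)
}

#' @export
summary.ncaseg <- function(object, ...) {
  np <- length(unlist(get_params(object$model)))
  out <- list(
    n_parameters = np,
    epochs = nrow(object$history),
    best_epoch = object$best_epoch,
    final = object$history[nrow(object$history), ],
    config = object$config
  )
  class(out) <- "summary.ncaseg"
  out
}

#' @export
print.summary.ncaseg <- function(x, ...) {
  cat(sprintf("ncaseg fit: %d parameters, %d epochs (best %d)\n",
              x$n_parameters, x$epochs, x$best_epoch))
  print(x$final, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ncaseg <- function(object, ...) {
  unlist(get_params(object$model))
}

#' Predict segmentation maps from a fitted model
#'
#' @param object A fitted [ncaseg()] object.
#' @param newdata A matrix, `phantom`, `phantom_dataset`, or list of these.
#' @param type `"prob"` for probability maps, `"mask"` for masks binarised
#'   at the model threshold.
#' @param n_e Pseudo-ensemble size: number of stochastic forward passes
#'   averaged per image; default 1.
#' @param seed Optional seed for the firing randomness.
#' @param preprocess Standardise inputs the way training did; default `TRUE`.
#' @param ... Unused.
#' @return A matrix for single-image input, otherwise a list of matrices.
#' @export
predict.ncaseg <- function(object, newdata, type = c("prob", "mask"),
                           n_e = 1, seed = NULL, preprocess = TRUE, ...) {
  type <- match.arg(type)
  imgs <- as_image_list(newdata, preprocess)
  single <- attr(imgs, "single")
  out <- with_seed(seed, lapply(imgs, function(im) {
    p <- if (n_e > 1) pseudo_ensemble(object, im, n_e,
                                      preprocess = FALSE)$mean_prob
         else forward_batch(object$model, list(im))[[1]]
    if (type == "mask") (p >= object$model$config$threshold) * 1 else p
  }))
  if (single) out[[1]] else out
}

as_image_list <- function(newdata, preprocess) {
  std <- function(im) if (preprocess)
    rescale_unit(clip_outliers(zscore_normalize(im), 5)) else im
  single <- FALSE
  if (inherits(newdata, "phantom_dataset")) newdata <- newdata$phantoms
  if (inherits(newdata, "phantom")) { newdata <- list(newdata); single <- TRUE }
  if (is.matrix(newdata)) { newdata <- list(newdata); single <- TRUE }
  imgs <- lapply(newdata, function(x)
    std(if (inherits(x, "phantom")) x$image else x))
  attr(imgs, "single") <- single
  imgs
}

#' Simulate stochastic segmentations from a fitted model
#'
#' Each simulation is one stochastic forward pass (one pseudo-ensemble
#' member) on the same input.
#'
#' @param object A fitted [ncaseg()] object.
#' @param nsim Number of stochastic forward passes; default 1.
#' @param seed Optional seed.
#' @param newdata Single image (matrix or `phantom`).
#' @param ... Unused.
#' @return List of `nsim` probability matrices.
#' @export
simulate.ncaseg <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  imgs <- as_image_list(newdata, TRUE)
  im <- imgs[[1]]
  with_seed(seed, lapply(seq_len(nsim), function(i)
    forward_batch(object$model, list(im))[[1]]))
}

#' Plot training history of a fitted model
#'
#' @param x A fitted [ncaseg()] object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.ncaseg <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = c(1, 2), col = c("black", "red"),
                    xlab = "epoch", ylab = "combined loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = c(1, 2),
                   col = c("black", "red"), bty = "n")
  invisible(x)
}

#' @export
print.ncaseg_model <- function(x, ...) {
  cat(sprintf("<ncaseg_model: %d levels, %d channels, %s>\n",
              x$config$n_levels + 1, x$coarse$C,
              if (x$config$use_sgb) "with SGB" else "no SGB"))
  invisible(x)
}
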