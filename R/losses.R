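#' Loss configuration for combined Dice + binary cross-entropy training
#'
#' @param alpha Weight on the Dice term, in \[0, 1\]; the combined loss is
#'   `alpha * dice_loss + (1 - alpha) * bce_loss`. Default 0.5.
#' @param epsilon Smoothing constant added to the soft-Dice numerator and
#'   denominator (> 0); default 1e-6.
#' @param prob_clip Probability clamp for the BCE logs, in (0, 0.5);
#'   default 1e-7.
#' @return Object of class `loss_config`.
#' @export
loss_config <- function(alpha = 0.5, epsilon = 1e-6, prob_clip = 1e-7) {
  if (alpha < 0 || alpha > 1) stopf("invalid config: alpha must be in [0, 1]")
  if (epsilon <= 0) stopf("invalid config: epsilon must be > 0")
  if (prob_clip <= 0 || prob_clip >= 0.5)
    stopf("invalid config: prob_clip must be in (0, 0.5)")
  structure(list(alpha = alpha, epsilon = epsilon, prob_clip = prob_clip),
            class = "loss_config")
}

check_shapes <- function(a, b) {
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b)))
    stopf("invalid argument: shape mismatch between prediction and target")
}

#' Dice overlap coefficient
#'
#' `2|P n G| / (|P| + |G|)`. With a binary `P` this is the hard Dice score;
#' with probabilities it is the soft variant (sums of probabilities). Two
#' empty masks score 1 by convention; `epsilon > 0` smooths the ratio for
#' differentiable training use.
#'
#' @param p Prediction, binary or probability matrix.
#' @param g Binary ground-truth matrix.
#' @param epsilon Smoothing constant (default 0: exact ratio).
#' @return Score in \[0, 1\].
#' @export
dice_coefficient <- function(p, g, epsilon = 0) {
  check_shapes(p, g)
  denom <- sum(p) + sum(g)
  if (denom == 0 && epsilon == 0) return(1)
  (2 * sum(p * g) + epsilon) / (denom + epsilon)
}

#' Dice loss: `1 - dice_coefficient`
#' @inheritParams dice_coefficient
#' @return Loss in \[0, 1\].
#' @export
dice_loss <- function(p, g, epsilon = 0) 1 - dice_coefficient(p, g, epsilon)

#' Binary cross-entropy
#'
#' `-(1/N) * sum(y*log(p) + (1-y)*log(1-p))` with probabilities clamped to
#' `[prob_clip, 1 - prob_clip]`.
#'
#' @param y Binary target matrix.
#' @param p Probability matrix.
#' @param prob_clip Clamp for the logs (default 1e-7).
#' @return Mean loss (>= 0).
#' @export
bce_loss <- function(y, p, prob_clip = 1e-7) {
  check_shapes(y, p)
  p <- pmin(pmax(p, prob_clip), 1 - prob_clip)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Combined Dice + BCE loss
#'
#' `alpha * dice_loss(soft, smoothed) + (1 - alpha) * bce_loss`; the training
#' objective balancing region overlap against pixel-wise accuracy.
#'
#' @param y Binary target matrix.
#' @param p Probability matrix.
#' @param cfg A [loss_config()].
#' @return Scalar loss.
#' @export
combined_loss <- function(y, p, cfg = loss_config()) {
  cfg$alpha * dice_loss(p, y, epsilon = cfg$epsilon) +
    (1 - cfg$alpha) * bce_loss(y, p, cfg$prob_clip)
}

#' Focal loss
#'
#' `-(1/N) * sum((1 - p_t)^gamma * log(p_t))` with
#' `p_t = p` where `y = 1` and `1 - p` otherwise. `gamma = 0` reduces to BCE.
#'
#' @param y Binary target matrix.
#' @param p Probability matrix.
#' @param gamma Focusing exponent (>= 0); default 2.
#' @param prob_clip Clamp for the logs.
#' @return Mean loss (>= 0).
#' @export
focal_loss <- function(y, p, gamma = 2, prob_clip = 1e-7) {
  check_shapes(y, p)
  if (gamma < 0) stopf("invalid argument: gamma must be >= 0")
  p <- pmin(pmax(p, prob_clip), 1 - prob_clip)
  pt <- ifelse(y == 1, p, 1 - p)
  -mean((1 - pt)^gamma * log(pt))
}

#' Mean intersection-over-union over foreground and background
#'
#' Per-class `|P n G| / |P u G|`, averaged over the two classes. A class
#' empty in both masks scores 1 by convention.
#'
#' @param pred Binary prediction matrix.
#' @param g Binary ground-truth matrix.
#' @return Score in \[0, 1\].
#' @export
miou <- function(pred, g) {
  check_shapes(pred, g)
  iou1 <- class_iou(pred, g)
  iou0 <- class_iou(1 - pred, 1 - g)
  (iou1 + iou0) / 2
}

class_iou <- function(p, g) {
  u <- sum(pmax(p, g))
  if (u == 0) return(1)
  sum(p * g) / u
}

#' Pixel accuracy
#'
#' Fraction of pixels where prediction and ground truth agree.
#'
#' @inheritParams miou
#' @return Fraction in \[0, 1\].
#' @export
pixel_accuracy <- function(pred, g) {
  check_shapes(pred, g)
  mean(pred == g)
}

mask_boundary <- function(m) {
  m <- m != 0
  h <- nrow(m); w <- ncol(m)
  below <- rbind(m[-1, , drop = FALSE], rep(FALSE, w))
  above <- rbind(rep(FALSE, w), m[-h, , drop = FALSE])
  right <- cbind(m[, -1, drop = FALSE], rep(FALSE, h))
  left <- cbind(rep(FALSE, h), m[, -w, drop = FALSE])
  m & !(below & above & left & right)
}

#' 95th-percentile Hausdorff distance between two binary masks
#'
#' Boundary pixels are mask pixels with at least one 4-neighbour outside the
#' mask (image borders count as outside). For each direction, the Euclidean
#' distance from every boundary pixel of one mask to the nearest boundary
#' pixel of the other is computed via an exact distance transform; the HD95
#' is the maximum of the two directed 95th percentiles, the dominant
#' convention in segmentation benchmarking.
#'
#' @param a,b Binary masks of identical shape, both non-empty.
#' @param spacing Physical size of one pixel (distance units/pixel);
#'   default 1 (HD95 in pixels).
#' @return Non-negative distance.
#' @export
hd95 <- function(a, b, spacing = 1) {
  check_shapes(a, b)
  if (sum(a != 0) == 0 || sum(b != 0) == 0)
    stopf("undefined metric: hd95 requires two non-empty masks")
  ba <- mask_boundary(a); bb <- mask_boundary(b)
  da <- directed_q95(ba, bb)
  db <- directed_q95(bb, ba)
  max(da, db) * spacing
}

directed_q95 <- function(from, to) {
  D <- as.matrix(EBImage::distmap(1 - to, metric = "euclidean"))
  stats::quantile(D[from], probs = 0.95, names = FALSE, type = 7)
}
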