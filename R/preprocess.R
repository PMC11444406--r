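#' Preprocessing configuration
#'
#' Defaults follow the standard chain for mammography-style input: resize to
#' 256 x 256, per-image z-normalisation, clamping of z-scores to +/- 5 to
#' remove values deviating strongly from the average, and rescaling to
#' \[0, 1\]. Elastic-deformation parameters apply to training-time
#' augmentation only, never at evaluation.
#'
#' @param target_size Length-2 integer target (rows, cols); default
#'   `c(256, 256)`.
#' @param clip_bound Z-score clamp bound (> 0); default 5.
#' @param elastic_alpha Displacement magnitude in pixels (default 34 at
#'   256 x 256 scale).
#' @param elastic_sigma Displacement smoothness in pixels (default 4).
#' @param seed Optional integer seed for the deformation field.
#' @return Object of class `preproc_config`.
#' @export
preproc_config <- function(target_size = c(256, 256), clip_bound = 5,
                           elastic_alpha = 34, elastic_sigma = 4,
                           seed = NULL) {
  if (length(target_size) != 2 || any(target_size < 1))
    stopf("invalid argument: target_size must be two positive integers")
  if (clip_bound <= 0) stopf("invalid argument: clip_bound must be > 0")
  structure(list(target_size = as.integer(target_size),
                 clip_bound = clip_bound, elastic_alpha = elastic_alpha,
                 elastic_sigma = elastic_sigma, seed = seed),
            class = "preproc_config")
}

#' Resize a 2D image
#'
#' Bilinear interpolation for images, nearest-neighbour for masks (which
#' keeps mask values binary).
#'
#' @param image Numeric matrix.
#' @param target Length-2 target size (rows, cols).
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return Numeric matrix of dimension `target`.
#' @export
resize_image <- function(image, target, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (length(dim(image)) != 2 || any(dim(image) == 0))
    stopf("invalid argument: image must be a non-empty matrix")
  if (length(target) != 2 || any(target < 1))
    stopf("invalid argument: target size must be positive")
  target <- as.integer(target)
  if (identical(dim(image), target)) return(image)
  filt <- if (method == "bilinear") "bilinear" else "none"
  as.matrix(EBImage::resize(image, w = target[1], h = target[2],
                            filter = filt))
}

#' Per-image z-normalisation
#'
#' Subtracts the mean and divides by the population standard deviation.
#'
#' @param image Numeric matrix with positive SD.
#' @return Matrix with mean 0 and population SD 1.
#' @export
zscore_normalize <- function(image) {
  m <- mean(image)
  s <- sqrt(mean((image - m)^2))
  if (s == 0) stopf("degenerate input: constant image has zero SD")
  (image - m) / s
}

#' Clamp z-scored values to a symmetric band
#'
#' Values inside `[-bound, bound]` pass through unchanged; values outside are
#' clamped to the bound, removing pixels that deviate strongly from the
#' average.
#'
#' @param image Numeric matrix (typically z-scored).
#' @param bound Positive clamp bound in z-units; default 5.
#' @return Clamped matrix.
#' @export
clip_outliers <- function(image, bound = 5) {
  if (bound <= 0) stopf("invalid argument: bound must be > 0")
  pmin(pmax(image, -bound), bound)
}

#' Affine rescale to the unit interval
#'
#' @param image Numeric matrix with `max > min`.
#' @return Matrix with min 0 and max 1.
#' @export
rescale_unit <- function(image) {
  r <- range(image)
  if (r[1] == r[2]) stopf("degenerate input: constant image cannot be rescaled")
  (image - r[1]) / (r[2] - r[1])
}

#' Full preprocessing chain
#'
#' resize (bilinear) -> z-normalise -> clamp outliers -> rescale to \[0, 1\].
#' If a mask is supplied it is resized with nearest-neighbour interpolation
#' and returned untouched otherwise, so it stays binary.
#'
#' @param image Numeric matrix.
#' @param cfg A [preproc_config()].
#' @param mask Optional binary matrix resized alongside the image.
#' @return The processed image, or `list(image, mask)` when a mask is given.
#' @export
preprocess_image <- function(image, cfg = preproc_config(), mask = NULL) {
  out <- resize_image(image, cfg$target_size)
  out <- rescale_unit(clip_outliers(zscore_normalize(out), cfg$clip_bound))
  if (is.null(mask)) return(out)
  m <- resize_image(mask, cfg$target_size, method = "nearest")
  list(image = out, mask = m)
}

#' Elastic deformation of an image/mask pair
#'
#' The classic augmentation: a random uniform displacement field smoothed by
#' a Gaussian of width `sigma` and scaled by `alpha`, applied identically to
#' the image (bilinear sampling) and the mask (nearest-neighbour sampling, so
#' mask values remain binary). Seeded and deterministic.
#'
#' @param image Numeric matrix.
#' @param mask Optional binary matrix of the same shape.
#' @param cfg A [preproc_config()] supplying `elastic_alpha`, `elastic_sigma`
#'   and `seed`; individual values can be overridden.
#' @param alpha,sigma,seed Overrides for the corresponding `cfg` fields.
#' @return `list(image, mask)` (mask `NULL` if not supplied).
#' @export
elastic_deform <- function(image, mask = NULL, cfg = preproc_config(),
                           alpha = cfg$elastic_alpha,
                           sigma = cfg$elastic_sigma, seed = cfg$seed) {
  if (!is.null(mask) && !identical(dim(image), dim(mask)))
    stopf("invalid argument: image and mask shapes differ")
  h <- nrow(image); w <- ncol(image)
  if (alpha == 0) return(list(image = image, mask = mask))
  field <- with_seed(seed, {
    list(dr = gauss_blur(matrix(stats::runif(h * w, -1, 1), h, w), sigma) * alpha,
         dc = gauss_blur(matrix(stats::runif(h * w, -1, 1), h, w), sigma) * alpha)
  })
  rows <- matrix(rep.int(seq_len(h), w), h, w)
  cols <- matrix(rep(seq_len(w), each = h), h, w)
  r <- rows + field$dr; c <- cols + field$dc
  img <- matrix(bilinear_sample(image, as.vector(r), as.vector(c)), h, w)
  mk <- NULL
  if (!is.null(mask)) {
    rn <- pmin(pmax(round(r), 1), h)
    cn <- pmin(pmax(round(c), 1), w)
    mk <- matrix(mask[cbind(as.vector(rn), as.vector(cn))], h, w)
  }
  list(image = img, mask = mk)
}
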