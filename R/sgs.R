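#' SLIC superpixel over-segmentation
#'
#' Simple Linear Iterative Clustering: k-means in (intensity, row, col) space
#' with a spatial search window of twice the expected superpixel spacing,
#' followed by enforcement of 4-connectivity (stray fragments are merged into
#' an adjacent superpixel). Intensities are internally rescaled to a 0-100
#' range so that `compactness = 10` balances intensity and space the way the
#' canonical algorithm does: low compactness adheres to intensity boundaries,
#' very high compactness degenerates toward rectangular tiles.
#'
#' @param image Numeric matrix (finite values).
#' @param K Requested number of superpixels (>= 1; at most the pixel count).
#'   The realised number `n_segments` may be smaller.
#' @param compactness Trade-off between spatial and intensity proximity;
#'   default 10.
#' @param max_iter Assignment/update iterations; default 10.
#' @return Object of class `superpixel_map`: list with `labels` (integer
#'   matrix, values in `0:(n_segments - 1)`), `n_segments`, `compactness`.
#' @export
slic_oversegment <- function(image, K, compactness = 10, max_iter = 10) {
  if (any(!is.finite(image))) stopf("invalid argument: image must be finite")
  h <- nrow(image); w <- ncol(image)
  if (K < 1 || K > h * w)
    stopf("invalid argument: K must be between 1 and the pixel count")
  K <- as.integer(K)
  rng <- range(image)
  img <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) * 100 else image * 0

  kr <- max(1L, as.integer(floor(sqrt(K * h / w))))
  kr <- min(kr, h, K)
  kc <- min(max(1L, K %/% kr), w)
  S <- sqrt(h * w / (kr * kc))
  cy <- (seq_len(kr) - 0.5) * h / kr
  cx <- (seq_len(kc) - 0.5) * w / kc
  centers <- cbind(r = rep(cy, times = kc), c = rep(cx, each = kr))
  ci <- img[cbind(pmax(1, round(centers[, 1])), pmax(1, round(centers[, 2])))]
  nk <- nrow(centers)

  lab <- .slic_iterate_cpp(as.vector(img), h, w, cbind(centers, ci),
                           S, compactness, max_iter)
  labm <- matrix(lab, h, w)
  labm <- enforce_connectivity(labm)
  structure(list(labels = labm - 1L, n_segments = max(labm),
                 compactness = compactness), class = "superpixel_map")
}

# Relabel to contiguous 1..K and merge 4-connected fragments that are not
# their label's largest component into an adjacent component's label.
enforce_connectivity <- function(labm) {
  h <- nrow(labm); w <- ncol(labm)
  for (pass in 1:8) {
    comp <- label_components(labm)
    ncomp <- max(comp)
    if (ncomp == 0) break
    sizes <- tabulate(comp, ncomp)
    complab <- integer(ncomp)
    complab[comp] <- labm                # label of each component
    main <- vapply(split(seq_len(ncomp), complab), function(ix)
      ix[which.max(sizes[ix])], integer(1))
    orphan <- setdiff(seq_len(ncomp), main)
    if (!length(orphan)) break
    # assign each orphan component the label of an adjacent pixel outside it
    right <- cbind(comp[, -1, drop = FALSE], comp[, w])
    below <- rbind(comp[-1, , drop = FALSE], comp[h, ])
    left <- cbind(comp[, 1], comp[, -w, drop = FALSE])
    above <- rbind(comp[1, ], comp[-h, , drop = FALSE])
    for (oc in orphan) {
      sel <- comp == oc
      nb <- c(right[sel], below[sel], left[sel], above[sel])
      nb <- nb[nb != oc]
      if (!length(nb)) next
      counts <- tabulate(nb, ncomp)
      labm[sel] <- complab[which.max(counts)]
    }
  }
  # contiguous relabel
  u <- sort(unique(as.vector(labm)))
  matrix(match(labm, u), nrow(labm), ncol(labm))
}

# 4-connected components of a label image (components split across distinct
# labels), via per-label binary labelling.
label_components <- function(labm) {
  comp <- matrix(0L, nrow(labm), ncol(labm))
  off <- 0L
  for (l in sort(unique(as.vector(labm)))) {
    b <- EBImage::bwlabel(labm == l)
    b <- matrix(as.integer(b), nrow(labm))
    sel <- b > 0L
    comp[sel] <- b[sel] + off
    off <- off + max(b)
  }
  comp
}

#' Mean-pool features within each superpixel
#'
#' The Superpixel Pooling Module: aggregates the feature vector of every
#' pixel of a superpixel into one vector per superpixel. The mean reduction
#' makes unpool-after-pool an orthogonal projection; max pooling is available
#' behind `reduce = "max"`.
#'
#' @param features Numeric array `(H, W, F)` (or an `(H, W)` matrix treated
#'   as F = 1), spatial dims matching the superpixel map.
#' @param sp A [slic_oversegment()] result.
#' @param reduce `"mean"` (default) or `"max"`.
#' @return Object of class `pooled_features`: a `(n_segments x F)` matrix
#'   with one row per label, row `k` holding the pooled vector of label
#'   `k - 1`; attribute `labels` gives the label order.
#' @export
superpixel_pool <- function(features, sp, reduce = c("mean", "max")) {
  reduce <- match.arg(reduce)
  stopifnot(inherits(sp, "superpixel_map"))
  if (is.matrix(features)) dim(features) <- c(dim(features), 1L)
  d <- dim(features)
  if (!identical(d[1:2], dim(sp$labels)))
    stopf("invalid argument: feature and superpixel map shapes differ")
  Fm <- matrix(features, d[1] * d[2], d[3])
  grp <- as.vector(sp$labels) + 1L
  pooled <- if (reduce == "mean") {
    rowsum(Fm, grp) / tabulate(grp, sp$n_segments)
  } else {
    do.call(rbind, lapply(seq_len(sp$n_segments), function(k)
      apply(Fm[grp == k, , drop = FALSE], 2, max)))
  }
  dimnames(pooled) <- NULL
  structure(pooled, labels = seq_len(sp$n_segments) - 1L,
            class = c("pooled_features", class(pooled)))
}

#' Broadcast pooled features back onto their superpixel supports
#'
#' The Shape-Shared Unpooling Module: output pixel `(h, w)` receives the
#' pooled row of `labels[h, w]`, producing a feature map piecewise constant
#' on superpixels.
#'
#' @param pooled A [superpixel_pool()] result (or a `(n_segments x F)`
#'   matrix with rows ordered by label).
#' @param sp The [slic_oversegment()] map the features were pooled over.
#' @return Numeric array `(H, W, F)`.
#' @export
shape_shared_unpool <- function(pooled, sp) {
  stopifnot(inherits(sp, "superpixel_map"))
  pooled <- unclass(pooled)
  if (nrow(pooled) < sp$n_segments)
    stopf("inconsistent input: pooled table lacks rows for some labels")
  d <- dim(sp$labels)
  out <- pooled[as.vector(sp$labels) + 1L, , drop = FALSE]
  array(out, c(d[1], d[2], ncol(pooled)))
}

#' Shape-guided refinement block (SGB)
#'
#' Composes SLIC over-segmentation of the guidance image with superpixel
#' pooling and shape-shared unpooling, and fuses the shape-smoothed features
#' back residually: `refined = features + unpool(pool(features))`. With the
#' residual combination a feature map that is already piecewise constant on
#' the superpixels is exactly doubled; white-noise features have their
#' within-superpixel variance reduced. Because the superpixels depend on the
#' guidance image only through intensity contrasts, adding a constant to the
#' image leaves the output unchanged.
#'
#' @param features Numeric array `(H, W, F)` or matrix.
#' @param image Guidance image (matrix, same spatial shape).
#' @param K Requested superpixel count.
#' @param compactness SLIC compactness; default 10.
#' @return Refined feature array `(H, W, F)`.
#' @export
shape_guided_block <- function(features, image, K, compactness = 10) {
  if (is.matrix(features)) dim(features) <- c(dim(features), 1L)
  if (!identical(dim(features)[1:2], dim(image)))
    stopf("invalid argument: feature and image shapes differ")
  sp <- slic_oversegment(image, K, compactness)
  features + shape_shared_unpool(superpixel_pool(features, sp), sp)
}

#' Shared per-pixel classification layer
#'
#' Applies one linear map (identical weights at every pixel) across the
#' feature channels, returning a logit map; probabilities are
#' `plogis(logits)`.
#'
#' @param features Numeric array `(H, W, F)` or matrix (F = 1).
#' @param weights List with `w` (length-F numeric) and `b` (scalar).
#' @return `(H, W)` logit matrix.
#' @export
shared_classification_layer <- function(features, weights) {
  if (is.matrix(features)) dim(features) <- c(dim(features), 1L)
  d <- dim(features)
  if (length(weights$w) != d[3])
    stopf("invalid argument: weight length %d != feature dimension %d",
          length(weights$w), d[3])
  Fm <- matrix(features, d[1] * d[2], d[3])
  matrix(Fm %*% weights$w + (weights$b %||% 0), d[1], d[2])
}
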