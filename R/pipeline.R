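#' Downscale a shape by repeated integer division
#'
#' Each dimension becomes `floor(dim / d^n)`; with the standard reduction
#' factor `d = 2` and `n = 4` iterations a `[640, 640, 48]` volume reduces to
#' `[40, 40, 3]`.
#'
#' @param shape Integer vector of dimensions.
#' @param d Downscaling factor (>= 1).
#' @param n Number of downsampling iterations (>= 0).
#' @return Integer vector of reduced dimensions.
#' @export
downscale_shape <- function(shape, d = 2, n = 1) {
  if (d < 1) stopf("invalid argument: d must be >= 1")
  if (n < 0) stopf("invalid argument: n must be >= 0")
  out <- as.integer(floor(shape / d^n))
  if (any(out < 1))
    stopf("invalid schedule: shape [%s] collapses below 1 at d=%s, n=%s",
          paste(shape, collapse = ", "), d, n)
  out
}

#' Downscale an image by area averaging
#'
#' Output shape is `downscale_shape(dim(image), d, n)`; each output pixel is
#' the mean of its source block (exact block mean when the sizes divide).
#'
#' @param image Numeric matrix.
#' @param d Downscaling factor (>= 1).
#' @param n Number of iterations (>= 0).
#' @return Reduced matrix.
#' @export
downscale_image <- function(image, d = 2, n = 1) {
  target <- downscale_shape(dim(image), d, n)
  if (identical(dim(image), target)) return(image)
  area_downscale(image, target[1], target[2])
}

downscale_mask <- function(mask, d = 2, n = 1) {
  m <- downscale_image(mask, d, n)
  (m >= 0.5) * 1
}

#' Upscale a mask or probability map
#'
#' Nearest-neighbour replication for masks (values stay binary, and an area
#' downscale by the same factor recovers the input exactly); bilinear
#' interpolation for probability maps.
#'
#' @param segmented Numeric matrix.
#' @param u,v Integer upscaling factors for rows and columns (>= 1).
#' @param method `"nearest"` (default) or `"bilinear"`.
#' @return Matrix of dimension `dim(segmented) * c(u, v)`.
#' @export
upscale_mask <- function(segmented, u, v = u, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  if (u < 1 || v < 1) stopf("invalid argument: upscale factors must be >= 1")
  u <- as.integer(u); v <- as.integer(v)
  h <- nrow(segmented); w <- ncol(segmented)
  if (method == "nearest") {
    idx <- upscale_index(h, w, 1L, h * u, w * v)
    matrix(segmented[idx], h * u, w * v)
  } else {
    as.matrix(EBImage::resize(segmented, w = h * u, h = w * v,
                              filter = "bilinear"))
  }
}

#' Aligned random crop of an image/mask pair
#'
#' Draws a uniformly random offset and crops both arrays identically,
#' recording the offset for reassembly.
#'
#' @param image Numeric matrix.
#' @param mask Matrix of the same shape (or `NULL`).
#' @param patch Length-1 or length-2 patch size (rows, cols).
#' @param seed Optional seed for the offset draw.
#' @return `list(image, mask, offset)` with a 0-based `offset = c(row, col)`.
#' @export
patchify <- function(image, mask = NULL, patch, seed = NULL) {
  if (length(patch) == 1) patch <- c(patch, patch)
  h <- nrow(image); w <- ncol(image)
  if (patch[1] > h || patch[2] > w)
    stopf("invalid argument: patch exceeds image size")
  if (!is.null(mask)) check_shapes(image, mask)
  off <- with_seed(seed, c(sample.int(h - patch[1] + 1L, 1L),
                           sample.int(w - patch[2] + 1L, 1L)) - 1L)
  rows <- off[1] + seq_len(patch[1])
  cols <- off[2] + seq_len(patch[2])
  list(image = image[rows, cols, drop = FALSE],
       mask = if (!is.null(mask)) mask[rows, cols, drop = FALSE],
       offset = off)
}

#' Duplicate every item of a batch m times
#'
#' Duplicates are bit-identical; downstream stochastic cell firing
#' de-correlates them, which stabilises NCA training.
#'
#' @param batch A list.
#' @param m Duplication factor (>= 1).
#' @return List of length `m * length(batch)` with each item repeated `m`
#'   times consecutively.
#' @export
batch_duplicate <- function(batch, m) {
  if (m < 1) stopf("invalid argument: duplication factor must be >= 1")
  rep(batch, each = as.integer(m))
}

#' Model configuration for the multi-scale shape-guided NCA
#'
#' @param n_hidden Hidden state channels; default 16.
#' @param hidden_width Dense-layer width of both rules; default 16.
#' @param fire_rate Per-cell update probability; default 0.5.
#' @param d Downscaling factor between scales; default 2.
#' @param n_levels Number of downsampling iterations (coarsest scale is
#'   `1/d^n_levels` of full resolution); default 2.
#' @param steps_coarse,steps_fine NCA iterations at the coarsest scale and at
#'   each finer scale; default 10 each.
#' @param use_sgb Apply the shape-guided block to the final full-resolution
#'   feature state before classification; default `TRUE`.
#' @param sgb_sp_area Target superpixel area in pixels for the SGB's SLIC
#'   over-segmentation (K is derived from the image area); default 64.
#' @param sgb_compactness SLIC compactness; default 10.
#' @param patch_cap Training-time patch size: finer levels larger than this
#'   are trained on aligned random crops of this size; default 32.
#' @param threshold Probability threshold for binarisation; default 0.5.
#' @param seed Seed for weight initialisation.
#' @return Object of class `ncaseg_model_config`.
#' @export
model_config <- function(n_hidden = 16, hidden_width = 16, fire_rate = 0.5,
                         d = 2, n_levels = 2, steps_coarse = 10,
                         steps_fine = 10, use_sgb = TRUE, sgb_sp_area = 64,
                         sgb_compactness = 10, patch_cap = 32,
                         threshold = 0.5, seed = 1L) {
  structure(as.list(environment()), class = "ncaseg_model_config")
}

#' Instantiate an untrained multi-scale NCA model
#'
#' @param config A [model_config()].
#' @return Object of class `ncaseg_model`: the coarse (k = 7 then 3) rule,
#'   the fine (k = 3) rule shared by all finer scales, the shared
#'   classification weights (small random values; with weights set to zero
#'   the model predicts probability 0.5 everywhere) and the configuration.
#' @export
new_model <- function(config = model_config()) {
  stopifnot(inherits(config, "ncaseg_model_config"))
  with_seed(config$seed, {
    coarse <- nca_rule("coarse", kernel = 7, kernel2 = 3,
                       n_hidden = config$n_hidden,
                       hidden_width = config$hidden_width,
                       fire_rate = config$fire_rate)
    fine <- nca_rule("fine", kernel = 3, n_hidden = config$n_hidden,
                     hidden_width = config$hidden_width,
                     fire_rate = config$fire_rate)
    structure(list(coarse = coarse, fine = fine,
                   clf = list(w = stats::rnorm(coarse$C, sd = 0.1), b = 0),
                   config = config), class = "ncaseg_model")
  })
}

# ---- internal stacked-batch plumbing -----------------------------------

stack_vec <- function(mats) unlist(lapply(mats, as.vector), use.names = FALSE)

# Row indices of an aligned (ph x pw) window at 0-based per-image offsets
# within a stacked (b, h, w) state.
crop_index <- function(h, w, b, ph, pw, offsets) {
  hw <- h * w
  unlist(lapply(seq_len(b), function(bi) {
    r0 <- offsets[bi, 1]; c0 <- offsets[bi, 2]
    base <- (bi - 1L) * hw
    as.vector(outer(r0 + seq_len(ph), (c0 + seq_len(pw) - 1L) * h, `+`)) + base
  }), use.names = FALSE)
}

model_levels <- function(model, shape) {
  cfg <- model$config
  n <- cfg$n_levels
  shapes <- lapply(0:n, function(i) downscale_shape(shape, cfg$d, i))
  if (any(shapes[[n + 1]] < model$coarse$k))
    stopf("invalid input: %dx%d image is below the coarsest-level minimum %d",
          shape[1], shape[2], model$coarse$k)
  shapes
}

sgb_k <- function(model, h, w) {
  max(2L, min(h * w, as.integer(round(h * w / model$config$sgb_sp_area))))
}

# Shape-guided pooling over a stacked batch: per-image SLIC labels on the
# guidance windows, then residual mean-pool/unpool over all channels.
sgb_groups <- function(model, guidance) {
  b <- length(guidance)
  npix <- nrow(guidance[[1]]) * ncol(guidance[[1]])
  grp <- integer(0)
  off <- 0L
  for (bi in seq_len(b)) {
    sp <- slic_oversegment(guidance[[bi]],
                           K = sgb_k(model, nrow(guidance[[bi]]),
                                     ncol(guidance[[bi]])),
                           compactness = model$config$sgb_compactness)
    grp <- c(grp, as.vector(sp$labels) + 1L + off)
    off <- off + sp$n_segments
  }
  list(grp = grp, counts = tabulate(grp, off))
}

sgb_apply <- function(S, groups) {
  pooled <- rowsum(S, groups$grp) / groups$counts
  S + pooled[groups$grp, , drop = FALSE]
}

# ---- inference ----------------------------------------------------------

#' Run the full multi-scale forward pass on one image
#'
#' Downscales to the coarsest level, runs the coarse NCA, then alternates
#' nearest-neighbour state upscaling with fine-scale NCA refinement over the
#' whole frame; at full resolution the shape-guided block (if enabled)
#' refines the final feature state, and the shared classification layer plus
#' a sigmoid yields the probability map. Stochastic cell firing makes the
#' output a random variable; fix `seed` for reproducibility or average runs
#' with [pseudo_ensemble()].
#'
#' @param model An `ncaseg_model` or a fitted [ncaseg()] object.
#' @param image Numeric matrix, preprocessed to \[0, 1\].
#' @param seed Optional seed for the firing randomness.
#' @return Probability matrix with the shape of `image`, values in (0, 1).
#' @export
forward_full <- function(model, image, seed = NULL) {
  if (inherits(model, "ncaseg")) model <- model$model
  stopifnot(inherits(model, "ncaseg_model"))
  with_seed(seed, forward_batch(model, list(image))[[1]])
}

forward_batch <- function(model, images) {
  cfg <- model$config
  b <- length(images)
  shape <- dim(images[[1]])
  shapes <- model_levels(model, shape)
  n <- cfg$n_levels
  imgs_l <- lapply(shapes, function(s)
    lapply(images, function(im) if (identical(dim(im), s)) im else
      area_downscale(im, s[1], s[2])))
  hc <- shapes[[n + 1]][1]; wc <- shapes[[n + 1]][2]
  S <- matrix(0, b * hc * wc, model$coarse$C)
  S[, 1] <- stack_vec(imgs_l[[n + 1]])
  S <- run_steps(S, model$coarse, hc, wc, b, cfg$steps_coarse,
                 tag = "c")$S
  h <- hc; w <- wc
  if (n >= 1) for (i in n:1) {
    th <- shapes[[i]][1]; tw <- shapes[[i]][2]
    S <- S[upscale_index(h, w, b, th, tw), , drop = FALSE]
    h <- th; w <- tw
    S[, 1] <- stack_vec(imgs_l[[i]])
    S <- run_steps(S, model$fine, h, w, b, cfg$steps_fine,
                   tag = paste0("f", i))$S
  }
  if (cfg$use_sgb) {
    groups <- sgb_groups(model, imgs_l[[1]])
    S <- sgb_apply(S, groups)
    S[, 1] <- stack_vec(imgs_l[[1]])
  }
  p <- sigmoid(as.vector(S %*% model$clf$w) + model$clf$b)
  lapply(seq_len(b), function(bi)
    matrix(p[(bi - 1) * h * w + seq_len(h * w)], h, w))
}

# Iterate `steps` stochastic NCA updates on a stacked state; optionally keep
# per-step tapes for backpropagation through time. The input-image channel
# (column 1) is reasserted after every step. Running batch-norm statistics
# are written back into `rule` and returned.
run_steps <- function(S, rule, h, w, b, steps, tag = "default",
                      training = FALSE, tape = FALSE) {
  tapes <- if (tape) vector("list", steps)
  img <- S[, 1]
  for (t in seq_len(steps)) {
    slot <- paste0(tag, "_s", t)
    rf <- rule_fwd(S, rule, h, w, b, training = training, tape = tape,
                   slot = slot)
    rule$stats[[slot]] <- rf$stats
    fire <- stats::runif(nrow(S)) < rule$fire_rate
    S <- S + fire * rf$U
    S[, 1] <- img
    if (tape) tapes[[t]] <- list(rt = rf$tape, fire = fire)
  }
  list(S = S, rule = rule, tapes = tapes)
}

# Backpropagate through `steps` NCA updates; returns the gradient w.r.t. the
# level's initial state plus accumulated rule-parameter gradients.
steps_bwd <- function(dS, tapes, rule, training = TRUE) {
  g <- NULL
  for (t in rev(seq_along(tapes))) {
    dS[, 1] <- 0
    dU <- tapes[[t]]$fire * dS
    bw <- rule_bwd(dU, tapes[[t]]$rt, rule, training = training)
    g <- if (is.null(g)) bw$g else add_grads(g, bw$g)
    dS <- dS + bw$dS
  }
  dS[, 1] <- 0
  list(dS = dS, g = g)
}

add_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

zero_like <- function(p) lapply(p, function(x) x * 0)

# Per-image combined soft-Dice + BCE loss of a stacked state under the
# shared classification layer, with its gradient w.r.t. the state and the
# classification weights. `weight` scales the contribution (1 / n_levels).
clf_loss <- function(S, y, clf, alpha, eps, prob_clip, b, weight) {
  n <- nrow(S)
  npix <- n / b
  f <- rep(seq_len(b), each = npix)
  z <- as.vector(S %*% clf$w) + clf$b
  p <- sigmoid(z)
  sp <- rowsum(p, f)[, 1]; sy <- rowsum(y, f)[, 1]
  spy <- rowsum(p * y, f)[, 1]
  num <- 2 * spy + eps; den <- sp + sy + eps
  dice_l <- 1 - num / den
  pc <- pmin(pmax(p, prob_clip), 1 - prob_clip)
  bce_l <- rowsum(-(y * log(pc) + (1 - y) * log(1 - pc)), f)[, 1] / npix
  loss <- mean(alpha * dice_l + (1 - alpha) * bce_l)
  dp_dice <- -2 * y / den[f] + (num / den^2)[f]
  dz <- weight / b * (alpha * dp_dice * p * (1 - p) +
                        (1 - alpha) * (p - y) / npix)
  list(loss = weight * loss,
       dS = outer(dz, clf$w),
       gw = as.vector(crossprod(S, dz)), gb = sum(dz),
       p = p, f = f)
}

# One full forward/backward pass over a duplicated minibatch: multi-scale
# forward with patchified fine levels, per-scale combined losses, and
# hand-written backpropagation through time, scales and the shape-guided
# block. Returns the mean loss, all parameter gradients, updated batch-norm
# statistics, and the hard Dice of the final patches as a training metric.
train_step <- function(model, images, masks, alpha = 0.5, eps = 1e-6,
                       prob_clip = 1e-7) {
  cfg <- model$config
  b <- length(images)
  shape <- dim(images[[1]])
  shapes <- model_levels(model, shape)
  n <- cfg$n_levels
  if (n >= 1 && any(shape %% cfg$d^n != 0))
    stopf("invalid input: training images must be divisible by d^n_levels")
  imgs_l <- lapply(shapes, function(s)
    lapply(images, function(im) if (identical(dim(im), s)) im else
      area_downscale(im, s[1], s[2])))
  masks_l <- lapply(shapes, function(s)
    lapply(masks, function(m) if (identical(dim(m), s)) m else
      (area_downscale(m, s[1], s[2]) >= 0.5) * 1))
  nl <- n + 1                       # number of scales
  wl <- 1 / nl                      # per-scale loss weight

  # ---- forward ----------------------------------------------------------
  hc <- shapes[[n + 1]][1]; wc <- shapes[[n + 1]][2]
  S <- matrix(0, b * hc * wc, model$coarse$C)
  S[, 1] <- stack_vec(imgs_l[[n + 1]])
  rs <- run_steps(S, model$coarse, hc, wc, b, cfg$steps_coarse,
                  tag = "c", training = TRUE, tape = TRUE)
  S <- rs$S
  model$coarse <- rs$rule
  levels_rec <- vector("list", nl)
  sgbt0 <- NULL
  if (n == 0 && cfg$use_sgb) {
    sgbt0 <- sgb_groups(model, imgs_l[[1]])
    S <- sgb_apply(S, sgbt0)
    S[, 1] <- stack_vec(imgs_l[[1]])
  }
  y <- stack_vec(masks_l[[n + 1]])
  cl <- clf_loss(S, y, model$clf, alpha, eps, prob_clip, b, wl)
  levels_rec[[n + 1]] <- list(tapes = rs$tapes, clf = cl, h = hc, w = wc,
                              sgb = sgbt0)
  offsets <- matrix(0L, b, 2)
  h <- hc; w <- wc
  if (n >= 1) for (i in n:1) {
    th <- h * cfg$d; tw <- w * cfg$d
    map <- upscale_index(h, w, b, th, tw)
    S <- S[map, , drop = FALSE]
    offsets <- offsets * cfg$d
    hl <- shapes[[i]][1]; wl_ <- shapes[[i]][2]
    # image channel over the current windows of the level-i image
    ci <- crop_index(hl, wl_, b, th, tw, offsets)
    imgvec <- stack_vec(imgs_l[[i]])
    S[, 1] <- imgvec[ci]
    crop <- NULL
    if (th > cfg$patch_cap) {
      ph <- cfg$patch_cap
      local_off <- cbind(sample.int(th - ph + 1L, b, replace = TRUE),
                         sample.int(tw - ph + 1L, b, replace = TRUE)) - 1L
      sel <- crop_index(th, tw, b, ph, ph, local_off)
      crop <- list(sel = sel, pre = c(th, tw))
      S <- S[sel, , drop = FALSE]
      offsets <- offsets + local_off
      th <- ph; tw <- ph
    }
    rs <- run_steps(S, model$fine, th, tw, b, cfg$steps_fine,
                    tag = paste0("f", i), training = TRUE, tape = TRUE)
    S <- rs$S
    model$fine <- rs$rule
    sgbt <- NULL
    if (i == 1 && cfg$use_sgb) {
      guidance <- lapply(seq_len(b), function(bi)
        imgs_l[[1]][[bi]][offsets[bi, 1] + seq_len(th),
                          offsets[bi, 2] + seq_len(tw), drop = FALSE])
      sgbt <- sgb_groups(model, guidance)
      S <- sgb_apply(S, sgbt)
      S[, 1] <- imgvec[crop_index(hl, wl_, b, th, tw, offsets)]
    }
    maskvec <- stack_vec(masks_l[[i]])
    y <- maskvec[crop_index(hl, wl_, b, th, tw, offsets)]
    cl <- clf_loss(S, y, model$clf, alpha, eps, prob_clip, b, wl)
    levels_rec[[i]] <- list(tapes = rs$tapes, clf = cl, h = th, w = tw,
                            map = map, crop = crop, sgb = sgbt)
    h <- th; w <- tw
  }
  loss <- sum(vapply(levels_rec, function(r) r$clf$loss, numeric(1)))

  # hard Dice of the final patches, one value per image
  pfin <- levels_rec[[1]]$clf$p
  ffin <- levels_rec[[1]]$clf$f
  dice_hard <- vapply(seq_len(b), function(bi) {
    sel <- ffin == bi
    dice_coefficient((pfin[sel] >= cfg$threshold) * 1, y[sel])
  }, numeric(1))

  # ---- backward ---------------------------------------------------------
  g <- list(coarse = zero_like(model$coarse$params),
            fine = zero_like(model$fine$params),
            clf = list(w = numeric(model$coarse$C), b = 0))
  dS <- NULL
  for (i in seq_len(nl)) {
    rec <- levels_rec[[i]]
    dS <- if (is.null(dS)) rec$clf$dS else dS + rec$clf$dS
    g$clf$w <- g$clf$w + rec$clf$gw
    g$clf$b <- g$clf$b + rec$clf$gb
    if (i == 1 && cfg$use_sgb) {
      dS[, 1] <- 0
      dS <- sgb_apply(dS, rec$sgb)   # projection is symmetric
    }
    rule <- if (i == nl) model$coarse else model$fine
    sb <- steps_bwd(dS, rec$tapes, rule)
    nm <- if (i == nl) "coarse" else "fine"
    g[[nm]] <- add_grads(g[[nm]], sb$g)
    dS <- sb$dS
    if (i < nl) {
      if (!is.null(rec$crop)) {
        full <- matrix(0, b * rec$crop$pre[1] * rec$crop$pre[2],
                       ncol(dS))
        full[rec$crop$sel, ] <- dS
        dS <- full
      }
      dS[, 1] <- 0
      dS <- rowsum(dS, rec$map)
    }
  }
  list(loss = loss, grads = g, model = model, dice = dice_hard)
}
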