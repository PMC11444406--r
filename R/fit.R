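#' Training configuration
#'
#' One *epoch* is one Adam update on one randomly sampled (and duplicated)
#' minibatch, the way NCA training runs are usually counted; the defaults
#' follow the reference training recipe (learning rate 0.000015625, up to
#' 3000 epochs, early stopping after 20 epochs without validation
#' improvement, checkpoints every 10 epochs).
#'
#' @param learning_rate Adam learning rate; default 0.000015625.
#' @param lr_decay Per-epoch multiplicative learning-rate decay in (0, 1];
#'   default 1 (constant rate).
#' @param max_epochs Maximum number of epochs; default 3000.
#' @param early_stop_patience Stop after this many epochs without
#'   improvement of the validation loss (>= 1); default 20.
#' @param checkpoint_every Keep a model snapshot every this many epochs;
#'   default 10.
#' @param batch_size Images sampled per minibatch (before duplication);
#'   default 4.
#' @param duplication Batch duplication factor m (each image repeated m
#'   times in the minibatch); default 2.
#' @param alpha Dice weight of the combined loss, in \[0, 1\]; default 0.5.
#' @param seed Master seed for the whole run (split, sampling, firing);
#'   default 1.
#' @param val_fraction Fraction of the data held out for early stopping;
#'   default 0.2.
#' @param val_every Validate every this many epochs; default 1.
#' @param val_max At most this many validation images are evaluated;
#'   default 16.
#' @param augment Apply elastic-deformation augmentation to training
#'   batches; default `TRUE`.
#' @param elastic_alpha,elastic_sigma Deformation magnitude/smoothness in
#'   pixels, at the training image scale; defaults 8 and 4.
#' @param grad_clip Global L2 gradient-norm clip; default 1.
#' @param checkpoint_path Optional file the latest snapshot is written to.
#' @return Object of class `ncaseg_train_config`.
#' @export
train_config <- function(learning_rate = 0.000015625, lr_decay = 1,
                         max_epochs = 3000,
                         early_stop_patience = 20, checkpoint_every = 10,
                         batch_size = 4, duplication = 2, alpha = 0.5,
                         seed = 1L, val_fraction = 0.2, val_every = 1,
                         val_max = 16, augment = TRUE, elastic_alpha = 8,
                         elastic_sigma = 4, grad_clip = 1,
                         checkpoint_path = NULL) {
  if (alpha < 0 || alpha > 1) stopf("invalid config: alpha must be in [0, 1]")
  if (early_stop_patience < 1) stopf("invalid config: patience must be >= 1")
  if (batch_size < 1 || duplication < 1)
    stopf("invalid config: batch_size and duplication must be >= 1")
  structure(as.list(environment()), class = "ncaseg_train_config")
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(params) {
  rapply(params, function(x) NULL, how = "replace")
}

adam_update <- function(params, grads, state, lr, t, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.list(p)) {
      r <- adam_update(p, grads[[nm]], state[[nm]], lr, t, beta1, beta2, eps)
      params[[nm]] <- r$params
      state[[nm]] <- r$state
    } else {
      g <- grads[[nm]]
      st <- state[[nm]]
      if (is.null(st)) st <- list(m = g * 0, v = g * 0)
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mh <- st$m / (1 - beta1^t)
      vh <- st$v / (1 - beta2^t)
      params[[nm]] <- p - lr * mh / (sqrt(vh) + eps)
      state[[nm]] <- st
    }
  }
  list(params = params, state = state)
}

grad_norm <- function(g) sqrt(sum(unlist(rapply(g, function(x)
  sum(x * x), how = "unlist"))))

scale_grads <- function(g, s) rapply(g, function(x) x * s, how = "replace")

get_params <- function(model) {
  list(coarse = model$coarse$params, fine = model$fine$params,
       clf = model$clf)
}

set_params <- function(model, params) {
  model$coarse$params <- params$coarse
  model$fine$params <- params$fine
  model$clf <- params$clf
  model
}

# ---- the fitting function ----------------------------------------------

#' Fit a multi-scale shape-guided NCA segmenter
#'
#' Trains the model on image/mask pairs with Adam on the combined
#' soft-Dice + binary-cross-entropy loss, computed on patch predictions at
#' every scale. Each minibatch is duplicated `duplication` times (stochastic
#' firing de-correlates the copies), optionally elastically deformed, pushed
#' through the multi-scale forward pass, and backpropagated through time,
#' scales and the shape-guided block. An 80/20 split of the supplied data
#' provides the validation loss monitored for early stopping; the returned
#' model is the best validation snapshot.
#'
#' @param x Training input: a [generate_dataset()] phantom dataset, a list
#'   of `phantom` objects, or a list of image matrices (then `masks` must be
#'   given).
#' @param masks Optional list of binary mask matrices matching `x`.
#' @param model A [model_config()] describing the architecture.
#' @param train A [train_config()] describing the optimisation.
#' @param preprocess Standardise each image (z-normalise, clamp outliers,
#'   rescale to \[0, 1\]) before training; default `TRUE`.
#' @return Object of class `ncaseg`: list with `model` (the trained
#'   `ncaseg_model`), `history` (one row per epoch: losses, Dice,
#'   validation metrics), `best_epoch`, `config` and `call`. Methods:
#'   [predict.ncaseg()], [simulate.ncaseg()], `print`, `summary`, `coef`,
#'   `plot`.
#' @examples
#' \donttest{
#' ds <- generate_dataset(phantom_spec(seed = 1), n = 20, seed = 1)
#' fit <- ncaseg(ds, model = model_config(n_hidden = 4, hidden_width = 8,
#'                                        steps_coarse = 4, steps_fine = 4),
#'               train = train_config(max_epochs = 5, learning_rate = 2e-3))
#' pr <- predict(fit, ds$phantoms[[1]])
#' }
#' @export
ncaseg <- function(x, masks = NULL, model = model_config(),
                   train = train_config(), preprocess = TRUE) {
  cl <- match.call()
  data <- as_training_pairs(x, masks, preprocess)
  if (length(data) == 0) stopf("invalid argument: empty dataset")
  mdl <- new_model(model)
  fitted <- train_loop(mdl, data, train)
  structure(list(model = fitted$model, history = fitted$history,
                 best_epoch = fitted$best_epoch,
                 config = list(model = model, train = train),
                 call = cl), class = "ncaseg")
}

as_training_pairs <- function(x, masks, preprocess) {
  std <- function(im) if (preprocess)
    rescale_unit(clip_outliers(zscore_normalize(im), 5)) else im
  if (inherits(x, "phantom_dataset")) x <- x$phantoms
  if (length(x) == 0) return(list())
  if (inherits(x[[1]], "phantom")) {
    return(lapply(x, function(p) list(image = std(p$image), mask = p$mask)))
  }
  if (is.matrix(x)) x <- list(x)
  if (is.null(masks)) stopf("invalid argument: masks are required")
  if (is.matrix(masks)) masks <- list(masks)
  if (length(x) != length(masks))
    stopf("invalid argument: %d images but %d masks", length(x), length(masks))
  lapply(seq_along(x), function(i)
    list(image = std(x[[i]]), mask = (masks[[i]] != 0) * 1))
}

train_loop <- function(model, data, cfg) {
  set.seed(cfg$seed)
  nd <- length(data)
  n_val <- min(max(if (nd > 1) 1 else 0, round(cfg$val_fraction * nd)), nd - 1)
  val_idx <- if (n_val > 0) sample.int(nd, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(nd), val_idx)
  val_idx <- utils::head(val_idx, cfg$val_max)

  adam <- adam_init(get_params(model))
  best_loss <- Inf
  best_epoch <- 0L
  best_params <- get_params(model)
  best_stats <- list(coarse = model$coarse$stats, fine = model$fine$stats)
  last_ckpt <- model
  hist <- vector("list", cfg$max_epochs)

  for (epoch in seq_len(cfg$max_epochs)) {
    take <- sample(tr_idx, min(cfg$batch_size, length(tr_idx)))
    batch <- batch_duplicate(data[take], cfg$duplication)
    if (cfg$augment && cfg$elastic_alpha > 0) {
      batch <- lapply(batch, function(it) {
        d <- elastic_deform(it$image, it$mask, alpha = cfg$elastic_alpha,
                            sigma = cfg$elastic_sigma)
        list(image = d$image, mask = d$mask)
      })
    }
    ts <- train_step(model, lapply(batch, `[[`, "image"),
                     lapply(batch, `[[`, "mask"), alpha = cfg$alpha)
    if (!is.finite(ts$loss)) {
      cond <- structure(
        class = c("ncaseg_training_failure", "error", "condition"),
        list(message = sprintf("training failure: non-finite loss at epoch %d (last good checkpoint attached)", epoch),
             call = NULL, model = last_ckpt,
             history = do.call(rbind, hist[seq_len(epoch - 1)])))
      stop(cond)
    }
    model <- ts$model                    # batch-norm statistics advanced
    gn <- grad_norm(ts$grads)
    g <- if (gn > cfg$grad_clip) scale_grads(ts$grads, cfg$grad_clip / gn)
         else ts$grads
    lr_now <- cfg$learning_rate * cfg$lr_decay^(epoch - 1)
    up <- adam_update(get_params(model), g, adam, lr_now, epoch)
    model <- set_params(model, up$params)
    adam <- up$state

    val_loss <- NA_real_; val_dice <- NA_real_
    if (length(val_idx) && epoch %% cfg$val_every == 0) {
      # fixed firing seed: the validation loss is a deterministic function
      # of the parameters, so early stopping reacts to the model, not to
      # firing noise; the training RNG stream is left untouched
      vm <- with_seed(cfg$seed + 77003L,
                      evaluate_pairs(model, data[val_idx], cfg$alpha))
      val_loss <- vm$loss; val_dice <- vm$dice
      if (val_loss < best_loss - 1e-9) {
        best_loss <- val_loss
        best_epoch <- epoch
        best_params <- get_params(model)
        best_stats <- list(coarse = model$coarse$stats,
                           fine = model$fine$stats)
      }
    }
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ts$loss,
                                train_dice = mean(ts$dice),
                                val_loss = val_loss, val_dice = val_dice)
    if (epoch %% cfg$checkpoint_every == 0) {
      last_ckpt <- model
      if (!is.null(cfg$checkpoint_path)) save_ncaseg(model, cfg$checkpoint_path)
    }
    if (length(val_idx) && best_epoch > 0 &&
        (epoch - best_epoch) >= cfg$early_stop_patience) break
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  if (best_epoch > 0) {
    model <- set_params(model, best_params)
    model$coarse$stats <- best_stats$coarse
    model$fine$stats <- best_stats$fine
  }
  list(model = model, history = history,
       best_epoch = if (best_epoch > 0) best_epoch else nrow(history))
}

# Full-frame validation: mean combined loss and hard Dice over pairs.
evaluate_pairs <- function(model, pairs, alpha, chunk = 8L) {
  losses <- numeric(0); dices <- numeric(0)
  lc <- loss_config(alpha = alpha)
  for (start in seq(1, length(pairs), by = chunk)) {
    sub <- pairs[start:min(start + chunk - 1, length(pairs))]
    probs <- forward_batch(model, lapply(sub, `[[`, "image"))
    for (j in seq_along(sub)) {
      losses <- c(losses, combined_loss(sub[[j]]$mask, probs[[j]], lc))
      dices <- c(dices,
                 dice_coefficient((probs[[j]] >= model$config$threshold) * 1,
                                  sub[[j]]$mask))
    }
  }
  list(loss = mean(losses), dice = mean(dices))
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file embedding the weights, batch-norm
#' statistics and the full model configuration; `load_ncaseg()` restores an
#' object whose forward passes are bit-identical to the saved model's under
#' the same seed.
#'
#' @param model An `ncaseg_model` or fitted `ncaseg` object.
#' @param path File path.
#' @return `save_ncaseg` invisibly returns `path`; `load_ncaseg` returns the
#'   saved object.
#' @export
save_ncaseg <- function(model, path) {
  obj <- list(format = "ncaseg-checkpoint", version = 1L, model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_ncaseg
#' @export
load_ncaseg <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "ncaseg-checkpoint"))
    stopf("format error: %s is not an ncaseg checkpoint", path)
  obj$model
}
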