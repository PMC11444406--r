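#' Create an NCA update rule
#'
#' An NCA rule is the small learned local update shared by every cell of the
#' grid. Two variants are used by the multi-scale model:
#'
#' * `"fine"` — the convolutional base block: a k x k perception convolution,
#'   a 1 x 1 dense mixing layer, batch normalisation and ReLU, followed by a
#'   final linear (no-activation) 1 x 1 projection back to the grid channels
#'   so that updates can be signed. The projection extends the
#'   ReLU-terminated base block, which on its own could never produce
#'   negative state deltas; this is standard NCA practice and required for
#'   stable convergence.
#' * `"coarse"` — the two-kernel model block
#'   `conv_k2(ReLU(BatchNorm(conv_k(.))))` with a wide first kernel (k = 7)
#'   for context and a small second kernel (k2 = 3), applied as one fused
#'   update at the coarsest scale.
#'
#' The final layer starts near zero (SD 0.02) so an untrained rule produces
#' almost-null updates — keeping early iterations stable — while still
#' letting gradients reach the hidden channels; batch normalisation keeps
#' running statistics that are used at inference.
#'
#' @param type `"fine"` or `"coarse"`.
#' @param kernel Odd perception kernel size (default 3 for fine, 7 for
#'   coarse).
#' @param kernel2 Odd second kernel of the coarse block (default 3).
#' @param c_in Number of input-image channels (currently 1).
#' @param n_hidden Number of hidden state channels; default 16.
#' @param hidden_width Channels of the dense layer; default 16.
#' @param fire_rate Per-cell update probability in (0, 1]; default 0.5.
#' @return Object of class `nca_rule`.
#' @export
nca_rule <- function(type = c("fine", "coarse"),
                     kernel = if (type == "coarse") 7L else 3L,
                     kernel2 = 3L, c_in = 1L, n_hidden = 16L,
                     hidden_width = 16L, fire_rate = 0.5) {
  type <- match.arg(type)
  kernel <- as.integer(kernel); kernel2 <- as.integer(kernel2)
  if (kernel %% 2 == 0 || kernel2 %% 2 == 0)
    stopf("invalid config: kernel sizes must be odd")
  if (fire_rate <= 0 || fire_rate > 1)
    stopf("invalid config: fire_rate must be in (0, 1]")
  C <- c_in + 1L + as.integer(n_hidden)
  Hd <- as.integer(hidden_width)
  params <- if (type == "fine") {
    list(Wp = matrix(stats::rnorm(kernel^2 * C * C, sd = 1 / sqrt(kernel^2 * C)),
                     kernel^2 * C, C),
         bp = numeric(C),
         Wd = matrix(stats::rnorm(C * Hd, sd = 1 / sqrt(C)), C, Hd),
         bd = numeric(Hd),
         gamma = rep(1, Hd), beta = numeric(Hd),
         Wo = matrix(stats::rnorm(Hd * C, sd = 0.02), Hd, C),
         bo = numeric(C))
  } else {
    list(W1 = matrix(stats::rnorm(kernel^2 * C * Hd, sd = 1 / sqrt(kernel^2 * C)),
                     kernel^2 * C, Hd),
         b1 = numeric(Hd),
         gamma = rep(1, Hd), beta = numeric(Hd),
         W2 = matrix(stats::rnorm(kernel2^2 * Hd * C, sd = 0.02),
                     kernel2^2 * Hd, C),
         b2 = numeric(C))
  }
  structure(list(type = type, k = kernel, k2 = kernel2, c_in = as.integer(c_in),
                 n_hidden = as.integer(n_hidden), C = C, hidden_width = Hd,
                 fire_rate = fire_rate, params = params,
                 stats = list()),
            class = "nca_rule")
}

#' Initialise a cell grid from one or more images
#'
#' The grid state holds, per pixel, the (immutable) input image channel, one
#' output-logit channel, and `n_hidden` hidden channels, all but the image
#' initialised to zero.
#'
#' @param images A numeric matrix, or a list of equally sized matrices
#'   (a batch).
#' @param n_hidden Number of hidden channels; default 16.
#' @return Object of class `cell_grid` with fields `state`
#'   (`(b*h*w) x C` matrix), `h`, `w`, `b`, `c_in`, `C`.
#' @export
cell_grid <- function(images, n_hidden = 16L) {
  if (is.matrix(images)) images <- list(images)
  h <- nrow(images[[1]]); w <- ncol(images[[1]])
  b <- length(images)
  C <- 1L + 1L + as.integer(n_hidden)
  S <- matrix(0, b * h * w, C)
  S[, 1] <- unlist(lapply(images, as.vector), use.names = FALSE)
  structure(list(state = S, h = h, w = w, b = b, c_in = 1L, C = C),
            class = "cell_grid")
}

#' Extract the grid state as an array
#'
#' @param grid A [cell_grid()].
#' @return Array `(h, w, C)` for a single-image grid, `(h, w, C, b)`
#'   otherwise.
#' @export
grid_array <- function(grid) {
  a <- array(aperm(array(grid$state, c(grid$h * grid$w, grid$b, grid$C)),
                   c(1, 3, 2)),
             c(grid$h, grid$w, grid$C, grid$b))
  if (grid$b == 1L) a <- array(a, dim(a)[1:3])
  a
}

# --- internal forward/backward for one rule application -----------------

rule_fwd <- function(S, rule, h, w, b, training = FALSE, tape = FALSE,
                     slot = "default") {
  p <- rule$params
  n <- nrow(S)
  st <- rule$stats[[slot]]
  if (rule$type == "fine") {
    A <- conv_fwd(S, h, w, b, rule$k, p$Wp, p$bp)
    D <- A %*% p$Wd + rep(p$bd, each = n)
    bn <- bn_fwd(D, p$gamma, p$beta, training, st)
    R <- bn$out
    relu <- R > 0
    R[!relu] <- 0
    U <- R %*% p$Wo + rep(p$bo, each = n)
    list(U = U, stats = bn$stats,
         tape = if (tape) list(S = S, A = A, D = bn$D, mu = bn$mu,
                               inv = bn$inv, relu = relu, R = R,
                               dims = c(h, w, b)))
  } else {
    A <- conv_fwd(S, h, w, b, rule$k, p$W1, p$b1)
    bn <- bn_fwd(A, p$gamma, p$beta, training, st)
    R <- bn$out
    relu <- R > 0
    R[!relu] <- 0
    U <- conv_fwd(R, h, w, b, rule$k2, p$W2, p$b2)
    list(U = U, stats = bn$stats,
         tape = if (tape) list(S = S, D = bn$D, mu = bn$mu, inv = bn$inv,
                               relu = relu, R = R, dims = c(h, w, b)))
  }
}

rule_bwd <- function(dU, tape, rule, training = FALSE) {
  p <- rule$params
  h <- tape$dims[1]; w <- tape$dims[2]; b <- tape$dims[3]
  if (rule$type == "fine") {
    gWo <- crossprod(tape$R, dU)
    gbo <- colSums(dU)
    dR <- tcrossprod(dU, p$Wo)
    dR[!tape$relu] <- 0
    bb <- bn_bwd(dR, tape$D, tape$mu, tape$inv, p$gamma, training)
    gWd <- crossprod(tape$A, bb$dD)
    gbd <- colSums(bb$dD)
    dA <- tcrossprod(bb$dD, p$Wd)
    cb <- conv_bwd(dA, tape$S, h, w, b, rule$k, p$Wp)
    list(dS = cb$dS,
         g = list(Wp = cb$dW, bp = cb$db, Wd = gWd, bd = gbd,
                  gamma = bb$dgamma, beta = bb$dbeta, Wo = gWo, bo = gbo))
  } else {
    cb2 <- conv_bwd(dU, tape$R, h, w, b, rule$k2, p$W2)
    dR <- cb2$dS
    dR[!tape$relu] <- 0
    bb <- bn_bwd(dR, tape$D, tape$mu, tape$inv, p$gamma, training)
    cb1 <- conv_bwd(bb$dD, tape$S, h, w, b, rule$k, p$W1)
    list(dS = cb1$dS,
         g = list(W1 = cb1$dW, b1 = cb1$db, gamma = bb$dgamma,
                  beta = bb$dbeta, W2 = cb2$dW, b2 = cb2$db))
  }
}

# --- exported single-rule operations ------------------------------------

#' Convolutional base block: compute the update field of a fine rule
#'
#' @param grid A [cell_grid()].
#' @param rule A fine-type [nca_rule()].
#' @param training Use batch statistics (`TRUE`) or running statistics
#'   (`FALSE`, default) in batch normalisation.
#' @return Update field with the same shape as [grid_array()] of the grid.
#' @export
conv_base_block <- function(grid, rule, training = FALSE) {
  stopifnot(inherits(grid, "cell_grid"), inherits(rule, "nca_rule"))
  if (any(!is.finite(grid$state))) stopf("numeric error: non-finite state")
  if (rule$type != "fine")
    stopf("invalid config: conv_base_block expects a fine rule")
  U <- rule_fwd(grid$state, rule, grid$h, grid$w, grid$b, training)$U
  update_as_array(U, grid)
}

#' Two-kernel NCA model block: compute the fused coarse update field
#'
#' Applies `conv_k2(ReLU(BatchNorm(conv_k(state))))` — a wide perception
#' kernel followed by a small one — as one fused update.
#'
#' @param grid A [cell_grid()].
#' @param rule A coarse-type [nca_rule()] (its `kernel`/`kernel2` pair,
#'   default 7 then 3, forms the ordered two-kernel block).
#' @inheritParams conv_base_block
#' @return Update field shaped like [grid_array()] of the grid.
#' @export
nca_block <- function(grid, rule, training = FALSE) {
  stopifnot(inherits(grid, "cell_grid"), inherits(rule, "nca_rule"))
  if (any(!is.finite(grid$state))) stopf("numeric error: non-finite state")
  if (rule$type != "coarse")
    stopf("invalid config: nca_block expects a coarse rule")
  U <- rule_fwd(grid$state, rule, grid$h, grid$w, grid$b, training)$U
  update_as_array(U, grid)
}

update_as_array <- function(U, grid) {
  a <- array(aperm(array(U, c(grid$h * grid$w, grid$b, grid$C)), c(1, 3, 2)),
             c(grid$h, grid$w, grid$C, grid$b))
  if (grid$b == 1L) a <- array(a, dim(a)[1:3])
  a
}

#' One stochastic NCA step
#'
#' Computes the rule's update field and adds it to the state at cells that
#' fire: each cell draws an independent Bernoulli(`fire_rate`) indicator,
#' shared across its channels (a cell fires as a unit). Input-image channels
#' are restored after the addition and are therefore never modified.
#'
#' @param grid A [cell_grid()].
#' @param rule An [nca_rule()] (fine or coarse).
#' @param training Batch-norm mode, see [conv_base_block()].
#' @return The updated `cell_grid`.
#' @export
nca_step <- function(grid, rule, training = FALSE) {
  stopifnot(inherits(grid, "cell_grid"), inherits(rule, "nca_rule"))
  U <- rule_fwd(grid$state, rule, grid$h, grid$w, grid$b, training)$U
  fire <- stats::runif(nrow(U)) < rule$fire_rate
  S <- grid$state + fire * U
  S[, seq_len(grid$c_in)] <- grid$state[, seq_len(grid$c_in)]
  grid$state <- S
  grid
}

#' Iterate an NCA rule for a fixed number of steps
#'
#' The s-fold composition of [nca_step()]; `steps = 0` is the identity.
#' Running `a` steps and then `b` steps on the result (with a continuous RNG
#' stream) is equivalent to a single run of `a + b` steps.
#'
#' @inheritParams nca_step
#' @param steps Number of steps (>= 0).
#' @param trajectory If `TRUE`, also return the list of intermediate grids.
#' @return The final `cell_grid`, or `list(grid, trajectory)` when
#'   `trajectory = TRUE`.
#' @export
nca_run <- function(grid, rule, steps, training = FALSE, trajectory = FALSE) {
  if (length(steps) != 1 || steps < 0)
    stopf("invalid argument: steps must be >= 0")
  traj <- if (trajectory) vector("list", steps)
  for (s in seq_len(steps)) {
    grid <- nca_step(grid, rule, training)
    if (trajectory) traj[[s]] <- grid
  }
  if (trajectory) list(grid = grid, trajectory = traj) else grid
}
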