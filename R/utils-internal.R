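# Internal numerical machinery shared by the NCA core and the multi-scale
# pipeline. Cell states live in "stacked matrix" form: a (N x C) matrix where
# N = batch * height * width, pixels ordered column-major per image (row
# fastest), images stacked along rows. All convolution/dense/batch-norm
# forward AND backward passes are written out by hand on top of BLAS matmuls.

.ncaseg_env <- new.env(parent = emptyenv())

.memo <- function(key, builder) {
  if (is.null(.ncaseg_env[[key]])) .ncaseg_env[[key]] <- builder()
  .ncaseg_env[[key]]
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

sigmoid <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# k x k convolution over the stacked state (compiled im2col + GEMM): S is
# (N x C), W is (k*k*C x P) with row (c-1)*k*k + j holding the weight for
# input channel c at neighbourhood offset j (row offset varying fastest).
conv_fwd <- function(S, h, w, b, k, W, bias) {
  .conv_fwd_cpp(S, W, bias, h, w, b, k)
}

conv_bwd <- function(dOut, S, h, w, b, k, W) {
  .conv_bwd_cpp(dOut, S, W, h, w, b, k)
}

# Batch normalisation over columns (channels); population statistics.
# `stats` is one running-statistics slot (list(mean, var)) or NULL, in which
# case fresh mean-0/var-1 statistics are used.
bn_fwd <- function(D, gamma, beta, training, stats, momentum = 0.1, eps = 1e-5) {
  if (is.null(stats))
    stats <- list(mean = numeric(ncol(D)), var = rep(1, ncol(D)))
  if (training) {
    mu <- colMeans(D)
    v <- colMeans(D * D) - mu * mu
    v[v < 0] <- 0
    stats$mean <- (1 - momentum) * stats$mean + momentum * mu
    stats$var <- (1 - momentum) * stats$var + momentum * v
  } else {
    mu <- stats$mean
    v <- stats$var
  }
  inv <- 1 / sqrt(v + eps)
  out <- .bn_scale_cpp(D, mu, inv, gamma, beta)
  list(out = out, D = D, mu = mu, inv = inv, stats = stats)
}

bn_bwd <- function(dY, D, mu, inv, gamma, training) {
  .bn_bwd_cpp(dY, D, mu, inv, gamma, training)
}

# Nearest-neighbour upscale map: index into the coarse (h x w) stack for every
# pixel of the (th x tw) target stack of b images. Exact block replication
# whenever th, tw are multiples of h, w.
upscale_index <- function(h, w, b, th, tw) {
  .memo(sprintf("uidx_%d_%d_%d_%d_%d", h, w, b, th, tw), function() {
    row_idx <- rep.int(seq_len(th), tw)
    col_idx <- rep(seq_len(tw), each = th)
    p <- (((row_idx - 1L) * h) %/% th + 1L) + (((col_idx - 1L) * w) %/% tw) * h
    idx <- p
    if (b > 1L) {
      idx <- unlist(lapply(seq_len(b), function(bi) p + (bi - 1L) * h * w))
    }
    as.integer(idx)
  })
}

# Area (block-mean) binning of an h x w matrix onto an oh x ow grid. Exact
# block mean whenever h, w are multiples of oh, ow.
bin_index <- function(h, w, oh, ow) {
  .memo(sprintf("bidx_%d_%d_%d_%d", h, w, oh, ow), function() {
    row_idx <- rep.int(seq_len(h), w)
    col_idx <- rep(seq_len(w), each = h)
    tr <- ((row_idx - 1L) * oh) %/% h + 1L
    tc <- ((col_idx - 1L) * ow) %/% w + 1L
    grp <- tr + (tc - 1L) * oh
    list(grp = as.integer(grp), counts = tabulate(grp, oh * ow))
  })
}

area_downscale <- function(x, oh, ow) {
  h <- nrow(x); w <- ncol(x)
  bi <- bin_index(h, w, oh, ow)
  sums <- rowsum(as.vector(x), group = bi$grp)
  out <- numeric(oh * ow)
  out[as.integer(rownames(sums))] <- sums
  matrix(out / bi$counts, oh, ow)
}

# Gaussian smoothing; sigma = 0 is the identity. The kernel is capped to
# the image size so small grids remain blurrable.
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  mx <- min(dim(x))
  if (mx %% 2L == 0L) mx <- mx - 1L
  r <- max(3L, min(r, mx))
  as.matrix(EBImage::gblur(x, sigma = sigma, radius = r))
}

# Bilinear sampling of matrix `x` at (possibly fractional) coordinates,
# clamped to the image domain.
bilinear_sample <- function(x, r, c) {
  h <- nrow(x); w <- ncol(x)
  r <- pmin(pmax(r, 1), h)
  c <- pmin(pmax(c, 1), w)
  r0 <- pmin(floor(r), h - 1L); r0[h == 1L] <- 1
  c0 <- pmin(floor(c), w - 1L); c0[w == 1L] <- 1
  fr <- r - r0; fc <- c - c0
  i00 <- r0 + (c0 - 1) * h
  v00 <- x[i00];       v10 <- x[i00 + ifelse(h > 1, 1, 0)]
  v01 <- x[i00 + ifelse(w > 1, h, 0)]
  v11 <- x[i00 + ifelse(h > 1, 1, 0) + ifelse(w > 1, h, 0)]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

# Evaluate an expression with a private RNG stream, restoring the caller's.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

is_binary <- function(x) all(x %in% c(0, 1))
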