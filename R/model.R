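# Fully-convolutional residual scorer. The pair tensor (L_T x L_Q x C) is
# treated as an image with C channels: a 1x1 input projection to n_filters,
# then n_blocks post-activation residual blocks (3x3 conv -> ELU -> 3x3
# conv, add identity skip, ELU), then a 1x1 convolution to one channel and
# a sigmoid. No dense layers, so the parameter count is independent of the
# protein lengths and the same network scores any template-query pair.
#
# Convolutions are realized as im2col gathers followed by BLAS matrix
# multiplication; gradients are hand-derived (col2im scatter for the input,
# transposed products for the weights). Spatial maps are stored as
# (L_T * L_Q) x channels matrices in column-major cell order.

#' Scorer configuration
#'
#' @param n_blocks number of residual blocks (default 16).
#' @param n_filters convolution filters per layer (default 16).
#' @param kernel odd kernel size (default 3).
#' @param activation nonlinearity name; only `"elu"` is implemented.
#' @param in_channels input channels (default 77, the pair-tensor layout).
#' @return A `scorer_config` list.
#' @export
scorer_config <- function(n_blocks = 16L, n_filters = 16L, kernel = 3L,
                          activation = "elu", in_channels = N_CHANNELS) {
  stopifnot(n_blocks >= 1, n_filters >= 1, kernel %% 2 == 1)
  if (activation != "elu") stop_format("only 'elu' activation is implemented")
  structure(list(n_blocks = as.integer(n_blocks),
                 n_filters = as.integer(n_filters),
                 kernel = as.integer(kernel),
                 activation = activation,
                 in_channels = as.integer(in_channels)),
            class = "scorer_config")
}

# ELU nonlinearity (alpha = 1) and derivative; hot path, so C++ backed.
elu <- function(x) elu_cpp(x)
elu_grad <- function(x) elu_grad_cpp(x)

# Variance-scaling (fan-in) initialization for a weight matrix of shape
# fan_in x fan_out.
init_weight <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(1 / fan_in)),
         fan_in, fan_out)
}

#' Build a residual convolutional scorer
#'
#' Parameters are drawn deterministically from `seed` with variance-scaling
#' fan-in initialization; two builds with the same config and seed are
#' identical.
#'
#' @param cfg a [scorer_config()].
#' @param seed integer seed for initialization.
#' @return A `threader_scorer` S3 object.
#' @export
build_scorer <- function(cfg = scorer_config(), seed = 1L) {
  kk <- cfg$kernel^2
  f <- cfg$n_filters
  params <- with_seed(seed, {
    blocks <- lapply(seq_len(cfg$n_blocks), function(b) {
      list(W1 = init_weight(kk * f, f), b1 = numeric(f),
           W2 = init_weight(kk * f, f), b2 = numeric(f))
    })
    list(W_in = init_weight(cfg$in_channels, f), b_in = numeric(f),
         blocks = blocks,
         W_out = init_weight(f, 1L), b_out = numeric(1L))
  })
  structure(list(cfg = cfg, params = params, seed = as.integer(seed)),
            class = "threader_scorer")
}

#' @export
print.threader_scorer <- function(x, ...) {
  cat(sprintf(paste0("<threader_scorer> %d residual blocks x 2 convs, ",
                     "%d filters, %dx%d kernels, %d input channels ",
                     "(%d parameters)\n"),
              x$cfg$n_blocks, x$cfg$n_filters, x$cfg$kernel, x$cfg$kernel,
              x$cfg$in_channels, parameter_count(x)))
  invisible(x)
}

#' Number of trainable parameters
#'
#' Independent of input size: the network is fully convolutional.
#'
#' @param scorer a `threader_scorer`.
#' @return Integer count of trainable scalars.
#' @export
parameter_count <- function(scorer) {
  sum(vapply(rapply(scorer$params, length, how = "unlist"),
             identity, numeric(1)))
}

# Precompute im2col gather indices for an LT x LQ canvas and a k x k
# kernel: an (LT*LQ) x k^2 integer matrix of source cell indices into a
# matrix with a zero row appended at position LT*LQ + 1 (out-of-bounds).
# Memoized on (LT, LQ, k): minibatches reuse the same canvas repeatedly.
.idx_cache <- new.env(parent = emptyenv())

im2col_index <- function(LT, LQ, k) {
  key <- paste(LT, LQ, k, sep = "x")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  idx <- im2col_index_build(LT, LQ, k)
  # keep the cache tiny: two canvases cover a padded batch plus validation
  if (length(ls(.idx_cache)) > 8) rm(list = ls(.idx_cache), envir = .idx_cache)
  .idx_cache[[key]] <- idx
  idx
}

im2col_index_build <- function(LT, LQ, k) {
  r <- (k - 1L) %/% 2L
  n <- LT * LQ
  ii <- rep(seq_len(LT), times = LQ)
  jj <- rep(seq_len(LQ), each = LT)
  idx <- matrix(0L, n, k * k)
  col <- 0L
  for (dj in -r:r) {
    for (di in -r:r) {
      col <- col + 1L
      si <- ii + di; sj <- jj + dj
      ok <- si >= 1L & si <= LT & sj >= 1L & sj <= LQ
      v <- rep(n + 1L, n)  # zero row
      v[ok] <- si[ok] + (sj[ok] - 1L) * LT
      idx[, col] <- v
    }
  }
  idx
}

# Forward 3x3 (or kxk) convolution. Xm: n x C map matrix; idx from
# im2col_index; W: (k^2*C) x F; b: length F. Returns list(Y, cols).
conv_forward <- function(Xm, idx, W, b) {
  conv_fwd_cpp(Xm, idx, W, b)
}

# Backward pass of conv_forward: the im2col buffer is recomputed from the
# saved layer input, so caches stay small (one n x F map per layer).
conv_backward <- function(dY, X_in, idx, W) {
  conv_bwd_cpp(dY, X_in, idx, W)
}

# Full forward pass. x: LT x LQ x C array. Returns logits and, when
# want_cache, every intermediate needed by scorer_backward.
scorer_forward <- function(scorer, x, want_cache = FALSE) {
  cfg <- scorer$cfg; pp <- scorer$params
  dims <- dim(x)
  if (dims[3] != cfg$in_channels)
    stop_format("input has %d channels, scorer expects %d",
                dims[3], cfg$in_channels)
  LT <- dims[1]; LQ <- dims[2]; n <- LT * LQ
  Xm <- matrix(as.vector(unclass(x)), n, dims[3])
  idx <- im2col_index(LT, LQ, cfg$kernel)
  h0_pre <- sweep(Xm %*% pp$W_in, 2, pp$b_in, "+")
  h <- elu(h0_pre)
  cache <- if (want_cache) list(Xm = Xm, idx = idx, h0_pre = h0_pre,
                                blocks = vector("list", cfg$n_blocks))
  for (b in seq_len(cfg$n_blocks)) {
    blk <- pp$blocks[[b]]
    c1 <- conv_forward(h, idx, blk$W1, blk$b1)
    a1 <- elu(c1)
    c2 <- conv_forward(a1, idx, blk$W2, blk$b2)
    pre_out <- c2 + h
    h_new <- elu(pre_out)
    if (want_cache)
      cache$blocks[[b]] <- list(h_in = h, c1_pre = c1, a1 = a1,
                                pre_out = pre_out)
    h <- h_new
  }
  z <- as.vector(h %*% pp$W_out) + pp$b_out
  if (want_cache) { cache$h_final <- h; cache$z <- z }
  list(z = matrix(z, LT, LQ), cache = cache, LT = LT, LQ = LQ)
}

# Backward pass from d(loss)/d(logits). Returns gradient list with the same
# shape as scorer$params.
scorer_backward <- function(scorer, fwd, dz) {
  cfg <- scorer$cfg; pp <- scorer$params; cache <- fwd$cache
  n <- fwd$LT * fwd$LQ
  dzv <- matrix(as.vector(dz), n, 1)
  g_out <- list(W_out = crossprod(cache$h_final, dzv), b_out = sum(dzv))
  g_blocks <- vector("list", cfg$n_blocks)
  dh <- dzv %*% t(pp$W_out)
  for (b in rev(seq_len(cfg$n_blocks))) {
    blk <- pp$blocks[[b]]; cb <- cache$blocks[[b]]
    d_pre <- dh * elu_grad(cb$pre_out)
    bk2 <- conv_backward(d_pre, cb$a1, cache$idx, blk$W2)
    d_c1 <- bk2$dX * elu_grad(cb$c1_pre)
    bk1 <- conv_backward(d_c1, cb$h_in, cache$idx, blk$W1)
    g_blocks[[b]] <- list(W1 = bk1$dW, b1 = bk1$db, W2 = bk2$dW, b2 = bk2$db)
    dh <- bk1$dX + d_pre  # skip connection
  }
  d_h0 <- dh * elu_grad(cache$h0_pre)
  # same element order as scorer$params, so flattened grads line up
  list(W_in = crossprod(cache$Xm, d_h0), b_in = colSums(d_h0),
       blocks = g_blocks, W_out = g_out$W_out, b_out = g_out$b_out)
}

#' Predict the aligning probability matrix
#'
#' Runs the scorer on a pair feature tensor; the sigmoid head guarantees
#' every entry lies strictly inside (0, 1). Deterministic: no stochastic
#' layers.
#'
#' @param scorer a `threader_scorer`.
#' @param x L_T x L_Q x in_channels array ([assemble_pair_tensor()]).
#' @param mask optional logical validity matrix, passed through unchanged.
#' @return An `align_prob_matrix`: list with `p` (L_T x L_Q) and `mask`.
#' @export
predict_matrix <- function(scorer, x, mask = NULL) {
  fwd <- scorer_forward(scorer, x, want_cache = FALSE)
  p <- 1 / (1 + exp(-fwd$z))
  if (is.null(mask)) mask <- matrix(TRUE, fwd$LT, fwd$LQ)
  structure(list(p = p, mask = mask), class = "align_prob_matrix")
}

#' @export
predict.threader_scorer <- function(object, x, mask = NULL, ...) {
  predict_matrix(object, x, mask)
}

#' Save / load a scorer checkpoint
#'
#' The checkpoint embeds the config; loading refuses a file whose config
#' hash does not match its stored parameters.
#'
#' @param scorer a `threader_scorer`.
#' @param path checkpoint file path.
#' @return `save_scorer` the path, `load_scorer` the scorer, invisibly/not.
#' @export
save_scorer <- function(scorer, path) {
  obj <- list(cfg = scorer$cfg, params = scorer$params, seed = scorer$seed,
              cfg_hash = config_hash(scorer$cfg))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_scorer
#' @export
load_scorer <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$cfg_hash, config_hash(obj$cfg)))
    stop_format("checkpoint config hash mismatch in %s", path)
  structure(list(cfg = obj$cfg, params = obj$params, seed = obj$seed),
            class = "threader_scorer")
}

config_hash <- function(cfg) {
  paste(cfg$n_blocks, cfg$n_filters, cfg$kernel, cfg$activation,
        cfg$in_channels, sep = "-")
}
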