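# Training: label construction from reference alignments, the
# length-weighted cross-entropy objective, the warmup + polynomial-decay
# learning-rate schedule, and an AdamW loop with zero-padded minibatches
# whose padded cells are excluded from the loss.

#' Label matrix from a reference alignment
#'
#' Cells on the reference alignment path carry their local TM-score weight;
#' every other cell is 0 (a negative). Weights are copied verbatim, never
#' renormalized.
#'
#' @param ref [reference_alignment].
#' @param L_T,L_Q template and query lengths.
#' @return L_T x L_Q numeric matrix with values in [0, 1].
#' @export
label_matrix <- function(ref, L_T, L_Q) {
  w <- matrix(0, L_T, L_Q)
  pr <- ref$pairs
  if (nrow(pr) > 0) {
    if (max(pr[, 1]) > L_T || max(pr[, 2]) > L_Q)
      stop_format("reference pair indices exceed matrix dimensions")
    if (anyDuplicated(pr[, 1]) || anyDuplicated(pr[, 2]))
      stop_format("duplicate row/column index in reference alignment")
    w[pr] <- ref$weights
  }
  w
}

#' TM-score-weighted cross-entropy alignment loss
#'
#' Per sample:
#' `(1 / (L_T * L_Q)) * sum_valid [ -L * w_ij * log p_ij
#'   - (1 - w_ij) * log(1 - p_ij) ]` with `L = (L_T + L_Q) / 2`, the mean
#' length, which up-weights the scarce positive cells against the
#' ~L_T x L_Q negatives. Padded (masked-out) cells are excluded and do not
#' enter the normalization: `L_T`/`L_Q` are the true lengths. Probabilities
#' are clamped to `[1e-7, 1 - 1e-7]` before the logarithms.
#'
#' @param p probability matrix (or `align_prob_matrix`).
#' @param w label matrix from [label_matrix()], same padded shape as `p`.
#' @param mask optional logical matrix marking valid (non-padded) cells.
#' @param L_T,L_Q true (unpadded) lengths; default: inferred from `mask`.
#' @return Scalar loss.
#' @export
alignment_loss <- function(p, w, mask = NULL, L_T = NULL, L_Q = NULL) {
  if (inherits(p, "align_prob_matrix")) {
    if (is.null(mask)) mask <- p$mask
    p <- p$p
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(p), ncol(p))
  if (!all(dim(p) == dim(w)) || !all(dim(p) == dim(mask)))
    stop_format("p, w and mask must share dimensions")
  if (is.null(L_T)) L_T <- sum(rowSums(mask) > 0)
  if (is.null(L_Q)) L_Q <- sum(colSums(mask) > 0)
  Lbar <- (L_T + L_Q) / 2
  eps <- 1e-7
  pc <- pmin(pmax(p[mask], eps), 1 - eps)
  wv <- w[mask]
  sum(-Lbar * wv * log(pc) - (1 - wv) * log1p(-pc)) / (L_T * L_Q)
}

# Gradient of alignment_loss with respect to the pre-sigmoid logits z
# (p = sigmoid(z)): d/dz = (1/(L_T L_Q)) * [ -L w (1 - p) + (1 - w) p ]
# on valid cells, 0 on padded cells.
alignment_loss_grad_z <- function(p, w, mask, L_T, L_Q) {
  Lbar <- (L_T + L_Q) / 2
  g <- (-Lbar * w * (1 - p) + (1 - w) * p) / (L_T * L_Q)
  g[!mask] <- 0
  g
}

#' Training configuration
#'
#' Defaults follow the published schedule: AdamW with weight decay 1e-4,
#' learning rate warmed up linearly from 0 to 0.01 over the first 2 epochs,
#' then decayed polynomially (power 1 by default) to 1e-4 over the
#' following 16 epochs, batch size 2.
#'
#' @param peak_lr peak learning rate (0.01).
#' @param final_lr floor learning rate after decay (1e-4).
#' @param warmup_epochs linear warmup length in epochs (2).
#' @param decay_epochs polynomial decay length in epochs (16).
#' @param weight_decay decoupled AdamW weight decay (1e-4).
#' @param batch_size minibatch size (2).
#' @param poly_power polynomial decay power (1 = linear).
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (default 3).
#' @param max_epochs cap on total epochs (default warmup + decay).
#' @param seed shuffling / batching seed.
#' @return A `train_config` list.
#' @export
train_config <- function(peak_lr = 0.01, final_lr = 1e-4,
                         warmup_epochs = 2L, decay_epochs = 16L,
                         weight_decay = 1e-4, batch_size = 2L,
                         poly_power = 1, early_stop_patience = 3L,
                         max_epochs = warmup_epochs + decay_epochs,
                         seed = 1L) {
  stopifnot(peak_lr > 0, final_lr > 0, warmup_epochs + decay_epochs >= 1,
            batch_size >= 1)
  structure(list(peak_lr = peak_lr, final_lr = final_lr,
                 warmup_epochs = warmup_epochs, decay_epochs = decay_epochs,
                 weight_decay = weight_decay, batch_size = batch_size,
                 poly_power = poly_power,
                 early_stop_patience = early_stop_patience,
                 max_epochs = max_epochs, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a (fractional) epoch
#'
#' Linear 0 -> `peak_lr` over the warmup, then
#' `(peak - final) * (1 - t)^power + final` where t is the completed
#' fraction of the decay phase; continuous at the boundary and clamped to
#' `final_lr` afterwards.
#'
#' @param epoch_fraction position in training, in epochs (0 = start).
#' @param cfg a [train_config()].
#' @return Learning rate.
#' @export
lr_at <- function(epoch_fraction, cfg) {
  stopifnot(epoch_fraction >= 0)
  if (epoch_fraction < cfg$warmup_epochs)
    return(cfg$peak_lr * epoch_fraction / cfg$warmup_epochs)
  t <- min((epoch_fraction - cfg$warmup_epochs) / cfg$decay_epochs, 1)
  (cfg$peak_lr - cfg$final_lr) * (1 - t)^cfg$poly_power + cfg$final_lr
}

# Zero-pad a sample (x, w, mask) to target spatial dims.
pad_sample <- function(sample, LT, LQ) {
  d <- dim(sample$x)
  if (d[1] == LT && d[2] == LQ) return(sample)
  x <- array(0, dim = c(LT, LQ, d[3]))
  x[seq_len(d[1]), seq_len(d[2]), ] <- sample$x
  w <- matrix(0, LT, LQ); w[seq_len(d[1]), seq_len(d[2])] <- sample$w
  mask <- matrix(FALSE, LT, LQ)
  mask[seq_len(d[1]), seq_len(d[2])] <- sample$mask
  list(x = x, w = w, mask = mask)
}

# Flatten params/grads for the AdamW state, preserving structure.
flatten_params <- function(p) unlist(p, use.names = FALSE)
unflatten_params <- function(template, v) {
  pos <- 0L
  walk <- function(tpl) {
    if (is.list(tpl)) return(lapply(tpl, walk))
    n <- length(tpl)
    out <- v[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (is.matrix(tpl)) dim(out) <- dim(tpl)
    out
  }
  walk(template)
}

#' Train a scorer with AdamW
#'
#' Minibatches (seeded shuffle, samples bucketed by area `L_T * L_Q` to
#' limit padding waste) are zero-padded to the largest sample in the batch;
#' padded cells are excluded from the loss and gradients. Decoupled weight
#' decay is applied to weights (not biases). The parameters with the best
#' validation loss are returned; training stops early once validation loss
#' has not improved for `early_stop_patience` epochs.
#'
#' @param scorer initial `threader_scorer`.
#' @param train_set,val_set lists of samples, each a list with `x` (pair
#'   tensor), `w` (label matrix) and `mask` (logical matrix).
#' @param cfg a [train_config()].
#' @param verbose print per-epoch losses.
#' @return List with `scorer` (best parameters) and `history` data.frame
#'   (epoch, lr, train_loss, val_loss).
#' @export
train_scorer <- function(scorer, train_set, val_set, cfg = train_config(),
                         verbose = FALSE) {
  if (length(train_set) == 0 || length(val_set) == 0)
    stop_format("empty training or validation set")
  theta <- flatten_params(scorer$params)
  m <- numeric(length(theta)); v <- numeric(length(theta))
  step <- 0L
  # weight-decay mask: decay weights, not biases
  decay_mask <- unlist(rapply(scorer$params, function(x) {
    rep(if (is.matrix(x)) 1 else 0, length(x))
  }, how = "unlist"), use.names = FALSE)
  n_train <- length(train_set)
  history <- NULL
  best_val <- Inf; best_theta <- theta; bad_epochs <- 0L
  val_loss_of <- function(th) {
    sc <- scorer; sc$params <- unflatten_params(scorer$params, th)
    mean(vapply(val_set, function(s) {
      pm <- predict_matrix(sc, s$x, s$mask)
      alignment_loss(pm$p, s$w, s$mask)
    }, numeric(1)))
  }
  for (epoch in seq_len(cfg$max_epochs)) {
    order_idx <- with_seed(derive_seed(cfg$seed, epoch), {
      areas <- vapply(train_set,
                      function(s) prod(dim(s$x)[1:2]), numeric(1))
      # shuffle, then stable-sort by area bucket so batches pad little
      sh <- sample.int(n_train)
      sh[order(floor(log2(areas[sh] + 1)))]
    })
    batches <- split(order_idx,
                     ceiling(seq_along(order_idx) / cfg$batch_size))
    epoch_loss <- 0
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      LT <- max(vapply(train_set[idx], function(s) dim(s$x)[1], numeric(1)))
      LQ <- max(vapply(train_set[idx], function(s) dim(s$x)[2], numeric(1)))
      sc <- scorer; sc$params <- unflatten_params(scorer$params, theta)
      grad_sum <- NULL; batch_loss <- 0
      for (si in idx) {
        s <- pad_sample(train_set[[si]], LT, LQ)
        true_LT <- sum(rowSums(s$mask) > 0)
        true_LQ <- sum(colSums(s$mask) > 0)
        fwd <- scorer_forward(sc, s$x, want_cache = TRUE)
        p <- 1 / (1 + exp(-fwd$z))
        batch_loss <- batch_loss +
          alignment_loss(p, s$w, s$mask, true_LT, true_LQ)
        dz <- alignment_loss_grad_z(p, s$w, s$mask, true_LT, true_LQ)
        g <- flatten_params(scorer_backward(sc, fwd, dz))
        grad_sum <- if (is.null(grad_sum)) g else grad_sum + g
      }
      grad <- grad_sum / length(idx)
      epoch_loss <- epoch_loss + batch_loss
      step <- step + 1L
      lr <- lr_at(epoch - 1 + bi / length(batches), cfg)
      # AdamW update with bias correction and decoupled weight decay
      m <- 0.9 * m + 0.1 * grad
      v <- 0.999 * v + 0.001 * grad^2
      mhat <- m / (1 - 0.9^step)
      vhat <- v / (1 - 0.999^step)
      theta <- theta - lr * (mhat / (sqrt(vhat) + 1e-8) +
                               cfg$weight_decay * decay_mask * theta)
    }
    train_loss <- epoch_loss / n_train
    val_loss <- val_loss_of(theta)
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr_at(epoch, cfg),
      train_loss = train_loss, val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %2d  lr %.5f  train %.5f  val %.5f",
                      epoch, lr_at(epoch, cfg), train_loss, val_loss))
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss; best_theta <- theta; bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= cfg$early_stop_patience) break
    }
  }
  out <- scorer
  out$params <- unflatten_params(scorer$params, best_theta)
  list(scorer = out, history = history, best_val_loss = best_val)
}
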