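# Feed-forward network engine.
#
# Images are handled as N x D row-major batches of column-major flattened
# (H, W, C) arrays.  Convolution is implemented by gather (im2col) plus one
# BLAS matrix product; max/average pooling by p^2 vectorized gathers.  This
# keeps every training step inside vectorized base R and makes runs exactly
# reproducible from a seed.

#' Network hyperparameters
#'
#' One configuration is shared by all pathway networks of an experiment; the
#' networks differ only in their output heads.
#'
#' @param conv_blocks List of convolution blocks, each
#'   `list(filters =, kernel =, pool =)` (valid 3x3 convolutions with ReLU,
#'   followed by max pooling).  May be empty for a dense-only trunk.
#' @param dense_widths Hidden dense layer widths (ReLU, dropout).
#' @param dropout Dropout rate on hidden dense layers (default 0.30; dense
#'   layers only).
#' @param batch_size Minibatch size (default 256).
#' @param learning_rate Initial Adam learning rate (default 0.001).
#' @param max_epochs Epoch budget.
#' @param patience Early-stopping patience, in epochs without a new best
#'   validation per-slot accuracy; the best weights are restored.
#' @param input_pool Fixed average-pooling factor applied to the input image
#'   before the trainable stack (1 = none).
#' @param common_dense Widths of the trainable common dense layers of a
#'   two-pathway network.
#' @return A `net_config` list.
#' @export
net_config <- function(conv_blocks = list(list(filters = 32, kernel = 3, pool = 2),
                                          list(filters = 64, kernel = 3, pool = 2)),
                       dense_widths = c(512, 256),
                       dropout = 0.30,
                       batch_size = 256,
                       learning_rate = 0.001,
                       max_epochs = 100,
                       patience = 10,
                       input_pool = 1,
                       common_dense = c(128)) {
  fail_unless(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  fail_unless(length(dense_widths) >= 1, "need at least one dense layer")
  structure(
    list(conv_blocks = conv_blocks, dense_widths = dense_widths,
         dropout = dropout, batch_size = as.integer(batch_size),
         learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
         patience = as.integer(patience), input_pool = as.integer(input_pool),
         common_dense = common_dense),
    class = "net_config"
  )
}

# ---- gather index builders -------------------------------------------------

# column-major flat index of (r, c, ch) in an (H, W, C) array
flat_idx <- function(r, c, ch, H, W) r + (c - 1) * H + (ch - 1) * H * W

conv_gather_idx <- function(H, W, C, K) {
  outH <- H - K + 1; outW <- W - K + 1
  fail_unless(outH >= 1 && outW >= 1,
              "input (%dx%d) smaller than receptive field (%dx%d)", H, W, K, K)
  rr <- rep(seq_len(outH), outW)
  cc <- rep(seq_len(outW), each = outH)
  ii <- integer(0)
  for (ch in seq_len(C)) {
    for (kc in seq_len(K)) {
      for (kr in seq_len(K)) {
        ii <- c(ii, flat_idx(rr + kr - 1, cc + kc - 1, ch, H, W))
      }
    }
  }
  list(ii = ii, outH = outH, outW = outW, P = outH * outW, Q = K * K * C)
}

pool_gather_idx <- function(H, W, C, p) {
  outH <- H %/% p; outW <- W %/% p
  fail_unless(outH >= 1 && outW >= 1, "pooling factor %d too large for %dx%d", p, H, W)
  rr <- rep(seq_len(outH), outW)
  cc <- rep(seq_len(outW), each = outH)
  idx <- vector("list", p * p)
  k <- 0
  for (oc in seq_len(p)) {
    for (or in seq_len(p)) {
      k <- k + 1
      blk <- integer(0)
      for (ch in seq_len(C)) {
        blk <- c(blk, flat_idx((rr - 1) * p + or, (cc - 1) * p + oc, ch, H, W))
      }
      idx[[k]] <- blk
    }
  }
  list(idx = idx, outH = outH, outW = outW, P = outH * outW)
}

he_init <- function(n_in, n_out) {
  matrix(rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
}

# ---- network construction --------------------------------------------------

# Build the layer stack for an input of shape (H, W); consumes RNG.
build_layers <- function(config, input_shape, head_sizes) {
  H <- input_shape[1]; W <- input_shape[2]; C <- 1L
  layers <- list()
  if (config$input_pool > 1) {
    g <- pool_gather_idx(H, W, C, config$input_pool)
    layers[[length(layers) + 1]] <- list(type = "avgpool", g = g,
                                         p = config$input_pool)
    H <- g$outH; W <- g$outW
  }
  for (blk in config$conv_blocks) {
    g <- conv_gather_idx(H, W, C, blk$kernel)
    layers[[length(layers) + 1]] <- list(
      type = "conv", g = g,
      W = he_init(g$Q, blk$filters), b = rep(0, blk$filters)
    )
    H <- g$outH; W <- g$outW; C <- as.integer(blk$filters)
    if (!is.null(blk$pool) && blk$pool > 1) {
      gp <- pool_gather_idx(H, W, C, blk$pool)
      layers[[length(layers) + 1]] <- list(type = "maxpool", g = gp, p = blk$pool)
      H <- gp$outH; W <- gp$outW
    }
  }
  d <- H * W * C
  for (w in config$dense_widths) {
    layers[[length(layers) + 1]] <- list(type = "dense", W = he_init(d, w),
                                         b = rep(0, w))
    d <- w
  }
  layers[[length(layers) + 1]] <- list(type = "heads",
                                       W = he_init(d, sum(head_sizes)),
                                       b = rep(0, sum(head_sizes)))
  layers
}

#' Build an untrained pathway network
#'
#' A convolutional/dense trunk shared by all pathways, plus `n_objects`
#' softmax heads of `n_classes` units each.  Trunk size is independent of
#' the task; only the heads differ.
#'
#' @param config A [net_config()].
#' @param n_objects Number of output slots (one head per slot).
#' @param n_classes Classes per head (at least 2).
#' @param input_shape `c(H, W)` canvas shape in pixels.
#' @param seed Integer seed for weight initialization.
#' @return A `pathway_net`.
#' @export
build_pathway <- function(config, n_objects, n_classes, input_shape, seed = 1L) {
  fail_unless(n_classes >= 2, "need at least 2 classes per head")
  head_sizes <- rep(as.integer(n_classes), n_objects)
  layers <- with_seed(seed, build_layers(config, input_shape, head_sizes))
  structure(
    list(input_shape = as.integer(input_shape), layers = layers,
         head_sizes = head_sizes, config = config),
    class = "pathway_net"
  )
}

n_params <- function(net) {
  sum(vapply(net$layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

# ---- forward / backward ----------------------------------------------------

softmax_heads <- function(Z, head_sizes) {
  off <- 0
  for (s in head_sizes) {
    blk <- Z[, off + seq_len(s), drop = FALSE]
    blk <- exp(blk - apply(blk, 1, max))
    Z[, off + seq_len(s)] <- blk / rowSums(blk)
    off <- off + s
  }
  Z
}

# Forward pass; returns activations and caches needed for the backward pass.
# `training` enables dropout (consumes RNG).
nn_forward <- function(layers, X, head_sizes, dropout = 0, training = FALSE,
                       stop_at = length(layers)) {
  caches <- vector("list", stop_at)
  A <- X
  for (i in seq_len(stop_at)) {
    l <- layers[[i]]
    if (l$type == "avgpool") {
      out <- 0
      for (k in seq_along(l$g$idx)) out <- out + A[, l$g$idx[[k]], drop = FALSE]
      A <- out / length(l$g$idx)
      caches[[i]] <- list()
    } else if (l$type == "maxpool") {
      M <- A[, l$g$idx[[1]], drop = FALSE]
      arg <- matrix(1L, nrow(M), ncol(M))
      for (k in seq_along(l$g$idx)[-1]) {
        Mk <- A[, l$g$idx[[k]], drop = FALSE]
        sel <- Mk > M
        M[sel] <- Mk[sel]
        arg[sel] <- k
      }
      caches[[i]] <- list(arg = arg, in_dim = ncol(A))
      A <- M
    } else if (l$type == "conv") {
      N <- nrow(A); P <- l$g$P; Q <- l$g$Q
      Acol <- matrix(A[, l$g$ii, drop = FALSE], N * P, Q)
      Z <- Acol %*% l$W
      Z <- Z + rep(l$b, each = N * P)
      mask <- Z > 0
      Z[!mask] <- 0
      caches[[i]] <- list(Acol = Acol, mask = mask, N = N, in_dim = ncol(A))
      A <- matrix(Z, N, P * ncol(l$W))
    } else if (l$type == "dense") {
      Z <- A %*% l$W
      Z <- Z + rep(l$b, each = nrow(A))
      mask <- Z > 0
      Z[!mask] <- 0
      drop_mask <- NULL
      if (training && dropout > 0) {
        keep <- 1 - dropout
        drop_mask <- matrix((runif(length(Z)) < keep) / keep, nrow(Z), ncol(Z))
        Z <- Z * drop_mask
      }
      caches[[i]] <- list(A_in = A, mask = mask, drop_mask = drop_mask)
      A <- Z
    } else if (l$type == "heads") {
      Z <- A %*% l$W
      Z <- Z + rep(l$b, each = nrow(A))
      caches[[i]] <- list(A_in = A)
      A <- softmax_heads(Z, head_sizes)
    }
  }
  list(out = A, caches = caches)
}

# Mean cross-entropy over samples, summed over heads, from probabilities.
nn_loss <- function(probs, Y, head_sizes) {
  N <- nrow(probs)
  off <- c(0, cumsum(head_sizes))
  loss <- 0
  for (h in seq_along(head_sizes)) {
    p <- probs[cbind(seq_len(N), off[h] + Y[, h])]
    loss <- loss - sum(log(pmax(p, 1e-12))) / N
  }
  loss
}

# Backward pass from one-hot targets; returns per-layer gradients
# (NULL for parameter-free layers).  `first_trainable` lets the caller skip
# input gradients below the first layer that has parameters.
nn_backward <- function(layers, fwd, Y, head_sizes) {
  n_layers <- length(layers)
  grads <- vector("list", n_layers)
  N <- nrow(fwd$out)
  off <- c(0, cumsum(head_sizes))
  dZ <- fwd$out
  for (h in seq_along(head_sizes)) {
    dZ[cbind(seq_len(N), off[h] + Y[, h])] <-
      dZ[cbind(seq_len(N), off[h] + Y[, h])] - 1
  }
  dZ <- dZ / N
  first_param <- which(vapply(layers, function(l) l$type %in% c("conv", "dense", "heads"),
                              logical(1)))[1]
  dA <- NULL
  for (i in rev(seq_len(n_layers))) {
    l <- layers[[i]]
    cache <- fwd$caches[[i]]
    if (l$type == "heads") {
      grads[[i]] <- list(dW = crossprod(cache$A_in, dZ), db = colSums(dZ))
      dA <- if (i > first_param) tcrossprod(dZ, l$W) else NULL
    } else if (l$type == "dense") {
      dZl <- dA
      if (!is.null(cache$drop_mask)) dZl <- dZl * cache$drop_mask
      dZl <- dZl * cache$mask
      grads[[i]] <- list(dW = crossprod(cache$A_in, dZl), db = colSums(dZl))
      dA <- if (i > first_param) tcrossprod(dZl, l$W) else NULL
    } else if (l$type == "conv") {
      Nn <- cache$N; P <- l$g$P; Q <- l$g$Q
      dYm <- matrix(dA, Nn * P, ncol(l$W))
      dYm <- dYm * cache$mask
      grads[[i]] <- list(dW = crossprod(cache$Acol, dYm), db = colSums(dYm))
      if (i > first_param) {
        dAcol <- matrix(tcrossprod(dYm, l$W), Nn, P * Q)
        dX <- matrix(0, Nn, cache$in_dim)
        for (q in seq_len(Q)) {
          cols <- l$g$ii[(q - 1) * P + seq_len(P)]
          dX[, cols] <- dX[, cols] + dAcol[, (q - 1) * P + seq_len(P)]
        }
        dA <- dX
      } else {
        dA <- NULL
      }
    } else if (l$type == "maxpool") {
      if (i > first_param || i == 1) {
        dX <- matrix(0, nrow(dA), cache$in_dim)
        for (k in seq_along(l$g$idx)) {
          sel <- cache$arg == k
          add <- dA
          add[!sel] <- 0
          dX[, l$g$idx[[k]]] <- dX[, l$g$idx[[k]]] + add
        }
        dA <- dX
      }
    } else if (l$type == "avgpool") {
      # always below the first trainable layer in this architecture
      dA <- NULL
    }
    if (is.null(dA) && i <= first_param) break
  }
  grads
}

# ---- optimization ----------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (is.null(l$W)) return(NULL)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
}

adam_step <- function(layers, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    if (is.null(grads[[i]]) || is.null(layers[[i]]$W)) next
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * grads[[i]]$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * grads[[i]]$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * grads[[i]]$db
    s$vb <- beta2 * s$vb + (1 - beta2) * grads[[i]]$db^2
    layers[[i]]$W <- layers[[i]]$W - lr * (s$mW / corr1) / (sqrt(s$vW / corr2) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}

# ---- prediction and accuracy -----------------------------------------------

#' Predict head probabilities
#'
#' @param net A `pathway_net` (trained or not).
#' @param X `N x D` input matrix, pixel values already scaled to `[0, 1]`.
#' @param batch_size Evaluation batch size.
#' @return `N x sum(head_sizes)` matrix of per-head softmax probabilities.
#' @export
net_predict <- function(net, X, batch_size = 1024L) {
  N <- nrow(X)
  out <- NULL
  for (start in seq(1, N, by = batch_size)) {
    idx <- start:min(N, start + batch_size - 1)
    fwd <- nn_forward(net$layers, X[idx, , drop = FALSE], net$head_sizes)
    out <- rbind(out, fwd$out)
  }
  out
}

# Per-slot accuracy from probability scores and integer class targets.
heads_accuracy <- function(scores, Y, head_sizes, per_image = FALSE) {
  off <- c(0, cumsum(head_sizes))
  corr <- matrix(FALSE, nrow(scores), length(head_sizes))
  for (h in seq_along(head_sizes)) {
    blk <- scores[, off[h] + seq_len(head_sizes[h]), drop = FALSE]
    corr[, h] <- max.col(blk, ties.method = "first") == Y[, h]
  }
  if (per_image) mean(rowSums(corr) == ncol(corr)) else mean(corr)
}

# Core training loop: Adam, minibatches, early stopping on validation
# per-slot accuracy with best-weight restoration.  Consumes RNG.
fit_net <- function(net, X, Y, Xval, Yval, verbose = FALSE) {
  cfg <- net$config
  state <- adam_init(net$layers)
  t <- 0
  best <- list(acc = -Inf, layers = net$layers, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_accuracy = numeric())
  N <- nrow(X)
  epoch <- 0L
  while (epoch < cfg$max_epochs) {
    epoch <- epoch + 1L
    perm <- sample.int(N)
    epoch_loss <- 0
    n_batches <- 0
    for (start in seq(1, N, by = cfg$batch_size)) {
      idx <- perm[start:min(N, start + cfg$batch_size - 1)]
      fwd <- nn_forward(net$layers, X[idx, , drop = FALSE], net$head_sizes,
                        dropout = cfg$dropout, training = TRUE)
      loss <- nn_loss(fwd$out, Y[idx, , drop = FALSE], net$head_sizes)
      if (!is.finite(loss)) {
        stop(sprintf("non-finite loss at epoch %d (lr %.3g, batch of %d)",
                     epoch, cfg$learning_rate, length(idx)), call. = FALSE)
      }
      epoch_loss <- epoch_loss + loss
      n_batches <- n_batches + 1
      grads <- nn_backward(net$layers, fwd, Y[idx, , drop = FALSE], net$head_sizes)
      t <- t + 1
      upd <- adam_step(net$layers, grads, state, t, cfg$learning_rate)
      net$layers <- upd$layers
      state <- upd$state
    }
    val_acc <- heads_accuracy(net_predict(net, Xval), Yval, net$head_sizes)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = epoch_loss / n_batches,
                                         val_accuracy = val_acc))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val acc %.4f", epoch,
                      epoch_loss / n_batches, val_acc))
    }
    if (val_acc > best$acc + 1e-12) {
      best <- list(acc = val_acc, layers = net$layers, epoch = epoch)
    } else if (epoch - best$epoch >= cfg$patience) {
      break
    }
  }
  net$layers <- best$layers
  list(net = net, best_val_accuracy = max(best$acc, 0), history = history)
}
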