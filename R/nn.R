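# A compact convolutional network framework: just what the two-step
# pipeline needs to train its test-scale backbone on a CPU. Convolutions
# are evaluated as matrix products over im2col patch matrices (C++ inner
# loops, BLAS matmul); gradients are hand-derived per layer. Activations
# are H x W x C arrays; parameters live in plain R lists so checkpoints are
# ordinary R objects.

he_init <- function(fan_in, n) rnorm(n, 0, sqrt(2 / fan_in))

layer_conv <- function(in_ch, out_ch, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  list(type = "conv", in_ch = in_ch, out_ch = out_ch, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad),
       W = matrix(he_init(k * k * in_ch, k * k * in_ch * out_ch),
                  k * k * in_ch, out_ch),
       b = rep(0, out_ch))
}

layer_relu <- function() list(type = "relu")

layer_flatten <- function() list(type = "flatten")

# global average pooling: H x W x C -> C (translation-invariant sums)
layer_gap <- function() list(type = "gap")

layer_dense <- function(in_n, out_n) {
  list(type = "dense", W = matrix(he_init(in_n, in_n * out_n), in_n, out_n),
       b = rep(0, out_n))
}

conv_forward <- function(layer, x) {
  d <- dim(x)
  cols <- im2col_cpp(as.numeric(x), d[1L], d[2L], d[3L], layer$k,
                     layer$stride, layer$pad)
  z <- cols %*% layer$W
  z <- sweep(z, 2L, layer$b, "+")
  oh <- (d[1L] + 2L * layer$pad - layer$k) %/% layer$stride + 1L
  ow <- (d[2L] + 2L * layer$pad - layer$k) %/% layer$stride + 1L
  list(out = array(z, dim = c(oh, ow, layer$out_ch)),
       cache = list(cols = cols, in_dim = d))
}

conv_backward <- function(layer, cache, dout) {
  d <- dim(dout)
  G <- matrix(as.numeric(dout), d[1L] * d[2L], d[3L])
  dW <- crossprod(cache$cols, G)
  db <- colSums(G)
  dcols <- tcrossprod(G, layer$W)
  dx <- col2im_cpp(dcols, cache$in_dim[1L], cache$in_dim[2L], cache$in_dim[3L],
                   layer$k, layer$stride, layer$pad)
  list(dW = dW, db = db, dx = dx)
}

net_forward <- function(net, x) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "conv") {
      r <- conv_forward(l, x); x <- r$out; caches[[i]] <- r$cache
    } else if (l$type == "relu") {
      caches[[i]] <- x > 0
      x <- x * caches[[i]]
    } else if (l$type == "flatten") {
      caches[[i]] <- dim(x)
      x <- as.numeric(x)
    } else if (l$type == "gap") {
      caches[[i]] <- dim(x)
      x <- colMeans(matrix(x, prod(dim(x)[1:2]), dim(x)[3L]))
    } else if (l$type == "dense") {
      caches[[i]] <- x
      x <- as.numeric(crossprod(l$W, x)) + l$b
    } else stop("unknown layer type: ", l$type)
  }
  list(out = x, caches = caches)
}

net_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    if (l$type == "conv") {
      g <- conv_backward(l, caches[[i]], dout)
      grads[[i]] <- g[c("dW", "db")]
      dout <- g$dx
    } else if (l$type == "relu") {
      dout <- dout * caches[[i]]
    } else if (l$type == "flatten") {
      dout <- array(dout, dim = caches[[i]])
    } else if (l$type == "gap") {
      d <- caches[[i]]
      dout <- array(rep(dout / prod(d[1:2]), each = prod(d[1:2])), dim = d)
    } else if (l$type == "dense") {
      x <- caches[[i]]
      grads[[i]] <- list(dW = outer(x, dout), db = dout)
      dout <- as.numeric(l$W %*% dout)
    }
  }
  list(grads = grads, dx = dout)
}

zero_grads <- function(net) {
  lapply(net$layers, function(l) {
    if (!is.null(l$W)) list(dW = l$W * 0, db = l$b * 0) else NULL
  })
}

add_grads <- function(acc, g) {
  for (i in seq_along(acc)) {
    if (!is.null(acc[[i]]) && !is.null(g[[i]])) {
      acc[[i]]$dW <- acc[[i]]$dW + g[[i]]$dW
      acc[[i]]$db <- acc[[i]]$db + g[[i]]$db
    }
  }
  acc
}

adam_init <- function(net) {
  list(t = 0L, m = lapply(net$layers, function(l) {
    if (!is.null(l$W)) list(W = l$W * 0, b = l$b * 0) else NULL
  }), v = lapply(net$layers, function(l) {
    if (!is.null(l$W)) list(W = l$W * 0, b = l$b * 0) else NULL
  }))
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (i in seq_along(net$layers)) {
    if (is.null(grads[[i]])) next
    for (p in c("W", "b")) {
      g <- if (p == "W") grads[[i]]$dW else grads[[i]]$db
      state$m[[i]][[p]] <- beta1 * state$m[[i]][[p]] + (1 - beta1) * g
      state$v[[i]][[p]] <- beta2 * state$v[[i]][[p]] + (1 - beta2) * g^2
      step <- lr * (state$m[[i]][[p]] / bc1) /
        (sqrt(state$v[[i]][[p]] / bc2) + eps)
      net$layers[[i]][[p]] <- net$layers[[i]][[p]] - step
    }
  }
  list(net = net, state = state)
}

# ---- DSNT head over a stack of heatmap channels -------------------------

# logits: h x w x K array -> list(coords K x 2, probs) via spatial softmax +
# coordinate expectation per channel.
dsnt_forward <- function(logits) {
  d <- dim(logits)
  gx <- grid_coordinate(seq_len(d[2L]) - 1, d[2L])
  gy <- grid_coordinate(seq_len(d[1L]) - 1, d[1L])
  probs <- array(0, d)
  coords <- matrix(0, d[3L], 2L)
  for (k in seq_len(d[3L])) {
    p <- normalize_heatmap(logits[, , k])
    probs[, , k] <- p
    coords[k, ] <- c(sum(colSums(p) * gx), sum(rowSums(p) * gy))
  }
  list(coords = coords, probs = probs)
}

# dcoords: K x 2 gradient of the loss wrt coordinates -> gradient wrt logits
dsnt_backward <- function(cache, dcoords) {
  d <- dim(cache$probs)
  gx <- grid_coordinate(seq_len(d[2L]) - 1, d[2L])
  gy <- grid_coordinate(seq_len(d[1L]) - 1, d[1L])
  gxm <- matrix(gx, d[1L], d[2L], byrow = TRUE)
  gym <- matrix(gy, d[1L], d[2L])
  dlogits <- array(0, d)
  for (k in seq_len(d[3L])) {
    p <- cache$probs[, , k]
    a <- gxm * dcoords[k, 1L] + gym * dcoords[k, 2L]
    dlogits[, , k] <- p * (a - sum(p * a))
  }
  dlogits
}

# ---- losses -------------------------------------------------------------

# masked mean Euclidean loss on K x 2 coordinate blocks; returns gradient
# wrt predictions alongside the value
coord_loss_grad <- function(pred, target, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, nrow(pred))
  dpred <- pred * 0
  if (!any(mask)) return(list(loss = 0, dpred = dpred))
  diff <- pred - target
  dist <- sqrt(rowSums(diff^2))
  m <- sum(mask)
  sel <- mask & dist > 1e-8
  dpred[sel, ] <- diff[sel, , drop = FALSE] / (dist[sel] * m)
  list(loss = sum(dist[mask]) / m, dpred = dpred)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

bce_loss_grad <- function(logits, targets) {
  p <- sigmoid(logits)
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  list(loss = -mean(targets * log(pc) + (1 - targets) * log(1 - pc)),
       dlogits = (p - targets) / length(logits))
}

# ---- generic trainer ----------------------------------------------------

#' Training schedule
#'
#' Mirrors the training recipe of the two-step pipeline: Adam at a fixed
#' starting learning rate, learning-rate reduction by `plateau_factor` when
#' the validation loss has not improved for `plateau_patience` epochs in a
#' row, and checkpointing of the epoch with the lowest validation loss.
#' The published full-scale recipes are lr 1e-4 / batch 16 for the presence
#' classifier and the refiner, and lr 1e-3 / batch 8 for the global corner
#' localizer, with 200 epochs; test-scale runs use far fewer epochs.
#'
#' @param learning_rate initial Adam learning rate.
#' @param batch_size gradients are accumulated over this many samples per
#'   update.
#' @param max_epochs number of epochs.
#' @param plateau_factor multiplicative LR decay on plateau.
#' @param plateau_patience epochs without improvement before decaying.
#' @param seed optional seed controlling shuffling and augmentation.
#' @export
train_schedule <- function(learning_rate = 1e-4, batch_size = 16L,
                           max_epochs = 200L, plateau_factor = 0.1,
                           plateau_patience = 10L, seed = NULL) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            plateau_factor > 0, plateau_factor < 1, plateau_patience >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 seed = seed),
            class = "train_schedule")
}

# step_fn(net, sample)  -> list(loss, grads)   (training pass)
# val_fn(net, sample)   -> loss                (evaluation pass)
# Returns list(net = best checkpoint, history, last_net).
train_loop <- function(net, train_samples, val_samples, step_fn, val_fn,
                       schedule, verbose = FALSE) {
  if (!length(train_samples)) stop("empty training set", call. = FALSE)
  state <- adam_init(net)
  lr <- schedule$learning_rate
  best <- list(loss = Inf, net = net)
  stall <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), lr = numeric())
  for (epoch in seq_len(schedule$max_epochs)) {
    ord <- sample.int(length(train_samples))
    acc <- zero_grads(net); nb <- 0L
    tr_loss <- 0
    for (idx in ord) {
      r <- step_fn(net, train_samples[[idx]])
      if (!is.finite(r$loss)) {
        stop(sprintf("non-finite training loss at epoch %d", epoch), call. = FALSE)
      }
      tr_loss <- tr_loss + r$loss
      acc <- add_grads(acc, r$grads); nb <- nb + 1L
      if (nb == schedule$batch_size) {
        for (i in seq_along(acc)) {
          if (!is.null(acc[[i]])) {
            acc[[i]]$dW <- acc[[i]]$dW / nb; acc[[i]]$db <- acc[[i]]$db / nb
          }
        }
        up <- adam_step(net, acc, state, lr)
        net <- up$net; state <- up$state
        acc <- zero_grads(net); nb <- 0L
      }
    }
    if (nb > 0L) {
      for (i in seq_along(acc)) {
        if (!is.null(acc[[i]])) {
          acc[[i]]$dW <- acc[[i]]$dW / nb; acc[[i]]$db <- acc[[i]]$db / nb
        }
      }
      up <- adam_step(net, acc, state, lr)
      net <- up$net; state <- up$state
    }
    vl <- if (length(val_samples)) {
      mean(vapply(val_samples, function(s) val_fn(net, s), numeric(1)))
    } else tr_loss / length(train_samples)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = tr_loss / length(train_samples),
      val_loss = vl, lr = lr))
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f  lr %.2g",
                      epoch, tr_loss / length(train_samples), vl, lr))
    }
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, net = net)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= schedule$plateau_patience) {
        lr <- lr * schedule$plateau_factor
        stall <- 0L
      }
    }
  }
  list(net = best$net, best_val = best$loss, history = history, last_net = net)
}
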