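#' Neural network configuration
#'
#' The dense acceptance classifier: three fully connected hidden layers of
#' 150 rectified units, dropout 0.24 after the first two, a single logistic
#' output trained with binary cross-entropy and L2 weight decay under Adam.
#' The learning rate starts at 1.5e-3 and is multiplied by 0.18 when the
#' validation loss fails to improve by `lr_min_delta` for `lr_patience`
#' consecutive epochs; training stops early after `stop_patience` epochs
#' without improvement (best weights restored).
#'
#' @param hidden units per hidden layer.
#' @param dropout dropout probability after each hidden layer.
#' @param l2 L2 regularization coefficient on the weights.
#' @param lr initial learning rate.
#' @param lr_factor multiplicative learning-rate reduction factor.
#' @param lr_min_delta minimum validation-loss improvement that resets the
#'   patience counters.
#' @param lr_patience epochs without improvement before a rate reduction.
#' @param stop_patience epochs without improvement before early stopping.
#' @param max_epochs maximum number of epochs.
#' @param batch_size mini-batch size.
#' @param seed optional integer seed (weight init, shuffling, dropout masks).
#' @return an `nn_config`.
#' @export
nn_config <- function(hidden = c(150, 150, 150), dropout = c(0.24, 0.24, 0),
                      l2 = 1e-4, lr = 1.5e-3, lr_factor = 0.18,
                      lr_min_delta = 0.01, lr_patience = 12,
                      stop_patience = 24, max_epochs = 1000, batch_size = 16,
                      seed = NULL) {
  stopifnot(length(dropout) == length(hidden), all(dropout >= 0 & dropout < 1),
            lr_patience > 0, stop_patience > 0, max_epochs > 0, batch_size > 0)
  structure(as.list(environment()), class = "nn_config")
}

relu <- function(x) x * (x > 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

init_layers <- function(d_in, hidden) {
  dims <- c(d_in, hidden, 1L)
  lapply(seq_len(length(dims) - 1), function(i) {
    list(W = matrix(rnorm(dims[i] * dims[i + 1], 0, sqrt(2 / dims[i])),
                    dims[i], dims[i + 1]),
         b = numeric(dims[i + 1]))
  })
}

nn_forward <- function(layers, x, dropout = NULL) {
  L <- length(layers)
  acts <- vector("list", L + 1)
  masks <- vector("list", L)
  acts[[1]] <- x
  for (i in seq_len(L)) {
    z <- acts[[i]] %*% layers[[i]]$W
    z <- sweep(z, 2, layers[[i]]$b, "+")
    if (i < L) {
      a <- relu(z)
      if (!is.null(dropout) && dropout[i] > 0) {
        m <- matrix(rbinom(length(a), 1, 1 - dropout[i]) / (1 - dropout[i]),
                    nrow(a), ncol(a))
        a <- a * m
        masks[[i]] <- m
      }
      acts[[i + 1]] <- a
    } else {
      acts[[i + 1]] <- sigmoid(z)
    }
  }
  list(acts = acts, masks = masks)
}

bce_loss <- function(p, y, layers, l2) {
  eps <- 1e-12
  data_loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  reg <- l2 * sum(vapply(layers, function(l) sum(l$W^2), numeric(1)))
  data_loss + reg
}

#' Train the dense acceptance network
#'
#' Mini-batch Adam with the schedule described in [nn_config()]. The
#' per-epoch history (losses, accuracies, learning rate) is recorded.
#'
#' @param x training predictor matrix.
#' @param y training labels (`"Accepted"`/`"Rejected"`).
#' @param xval,yval validation split (disjoint from training).
#' @param config an [nn_config()].
#' @return a `track_nn` with fitted weights and `history` data frame.
#' @export
nn_train <- function(x, y, xval, yval, config = nn_config()) {
  x <- as.matrix(x); xval <- as.matrix(xval)
  y01 <- as.numeric(normalize_labels(y) == "Accepted")
  yval01 <- as.numeric(normalize_labels(yval) == "Accepted")
  n <- nrow(x)
  with_seed(config$seed, {
    layers <- init_layers(ncol(x), config$hidden)
    adam <- lapply(layers, function(l) {
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    })
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t <- 0
    lr <- config$lr
    best_loss <- Inf; best_layers <- layers
    wait <- 0L; lr_wait <- 0L
    hist_rows <- vector("list", config$max_epochs)
    n_epochs <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        xb <- x[idx, , drop = FALSE]; yb <- y01[idx]
        fw <- nn_forward(layers, xb, dropout = config$dropout)
        L <- length(layers)
        p <- fw$acts[[L + 1]]
        # gradient of mean BCE wrt pre-sigmoid logits
        delta <- (p - yb) / length(yb)
        for (i in L:1) {
          a_prev <- fw$acts[[i]]
          gW <- crossprod(a_prev, delta) + 2 * config$l2 * layers[[i]]$W
          gb <- colSums(delta)
          if (i > 1) {
            delta <- delta %*% t(layers[[i]]$W)
            act <- fw$acts[[i]]  # post-dropout; shares the > 0 pattern
            if (!is.null(fw$masks[[i - 1]])) delta <- delta * fw$masks[[i - 1]]
            delta <- delta * (act > 0)
          }
          adam[[i]]$mW <- beta1 * adam[[i]]$mW + (1 - beta1) * gW
          adam[[i]]$vW <- beta2 * adam[[i]]$vW + (1 - beta2) * gW^2
          adam[[i]]$mb <- beta1 * adam[[i]]$mb + (1 - beta1) * gb
          adam[[i]]$vb <- beta2 * adam[[i]]$vb + (1 - beta2) * gb^2
        }
        t <- t + 1
        corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
        for (i in seq_len(L)) {
          layers[[i]]$W <- layers[[i]]$W -
            lr * (adam[[i]]$mW / corr1) / (sqrt(adam[[i]]$vW / corr2) + eps)
          layers[[i]]$b <- layers[[i]]$b -
            lr * (adam[[i]]$mb / corr1) / (sqrt(adam[[i]]$vb / corr2) + eps)
        }
      }
      ptr <- nn_forward(layers, x)$acts[[length(layers) + 1]]
      pva <- nn_forward(layers, xval)$acts[[length(layers) + 1]]
      train_loss <- bce_loss(ptr, y01, layers, config$l2)
      val_loss <- bce_loss(pva, yval01, layers, config$l2)
      if (!is.finite(train_loss) || !is.finite(val_loss)) {
        .stopf("training diverged at epoch %d (non-finite loss)", epoch)
      }
      hist_rows[[epoch]] <- data.frame(
        epoch = epoch, lr = lr,
        train_loss = train_loss, train_acc = mean((ptr > 0.5) == y01),
        val_loss = val_loss, val_acc = mean((pva > 0.5) == yval01))
      n_epochs <- epoch
      if (val_loss < best_loss - config$lr_min_delta) {
        best_loss <- val_loss; best_layers <- layers
        wait <- 0L; lr_wait <- 0L
      } else {
        if (val_loss < best_loss) {  # small improvement: keep weights anyway
          best_loss <- val_loss; best_layers <- layers
        }
        wait <- wait + 1L; lr_wait <- lr_wait + 1L
        if (lr_wait >= config$lr_patience) {
          lr <- lr * config$lr_factor
          lr_wait <- 0L
        }
        if (wait >= config$stop_patience) break
      }
    }
    structure(list(layers = best_layers, config = config,
                   history = do.call(rbind, hist_rows[seq_len(n_epochs)]),
                   n_epochs = n_epochs),
              class = "track_nn")
  })
}

#' @export
predict.track_nn <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != nrow(object$layers[[1]]$W)) {
    .stopf("predictor matrix has %d columns but the network expects %d",
           ncol(x), nrow(object$layers[[1]]$W))
  }
  as.numeric(nn_forward(object$layers, x)$acts[[length(object$layers) + 1]])
}

#' @export
print.track_nn <- function(x, ...) {
  cat(sprintf("<track_nn> %s units, trained %d epoch(s), best val loss %.4f\n",
              paste(x$config$hidden, collapse = "-"), x$n_epochs,
              min(x$history$val_loss)))
  invisible(x)
}
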