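# Supervised training (softmax cross-entropy, SGD with momentum).
#
# Inputs are prepared lazily per minibatch from compact rendered fields:
# crop pyramids for the scale-channel model, the resampled full field for the
# single-scale control. Training is deterministic given the seed.

prep_inputs_enn <- function(images, config) {
  g <- config$pyramid$common_grid
  nch <- config$pyramid$n_channels
  B <- length(images)
  arr <- array(0, c(g, g, nch, B))
  for (i in seq_len(B)) {
    arr[, , , i] <- sample_pyramid(network_input(images[[i]]),
                                   config$pyramid)$channels
  }
  arr
}

prep_inputs_cnn <- function(images, config) {
  m <- config$input_px
  B <- length(images)
  arr <- array(0, c(m, m, 1L, B))
  for (i in seq_len(B)) {
    arr[, , 1L, i] <- cnn_input(network_input(images[[i]]), config)
  }
  arr
}

prep_inputs <- function(model, images) {
  if (inherits(model, "enn_model")) prep_inputs_enn(images, model$config)
  else prep_inputs_cnn(images, model$config)
}

forward_backward <- function(model, X, labels) {
  cfg <- model$config
  w <- model$weights
  if (inherits(model, "enn_model")) {
    r <- enn_forward_core(X, w, cfg, keep_cache = TRUE)
    sm <- softmax_xent(r$scores, labels)
    dpooled <- w$fc$W %*% sm$dscores
    dW_fc <- r$pooled %*% t(sm$dscores)
    db_fc <- rowSums(sm$dscores)
    len <- cfg$feature_len; nch <- r$nch; B <- r$B
    dbank <- array(0, c(len, nch, B))
    for (k in seq_len(nch)) {
      dbank[, k, ] <- dpooled * (r$amax == k)
    }
    dOut <- dbank
    dim(dOut) <- c(cfg$dims$out_side, cfg$dims$out_side,
                   cfg$dims$out_filters, nch * B)
    sb <- stack_backward(dOut, r$caches, cfg$arch)
    probs <- sm$probs
  } else {
    r <- cnn_forward_core(X, w, cfg, keep_cache = TRUE)
    sm <- softmax_xent(r$scores, labels)
    dfeat <- w$fc$W %*% sm$dscores
    dW_fc <- r$feature %*% t(sm$dscores)
    db_fc <- rowSums(sm$dscores)
    dOut <- dfeat
    dim(dOut) <- c(cfg$dims$out_side, cfg$dims$out_side,
                   cfg$dims$out_filters, dim(X)[4L])
    sb <- stack_backward(dOut, r$caches, cfg$arch)
    probs <- sm$probs
  }
  list(loss = sm$loss, probs = probs,
       grads = list(conv = sb$grads, fc = list(dW = dW_fc, db = db_fc)))
}

predict_scores <- function(model, X) {
  if (inherits(model, "enn_model")) {
    enn_forward_core(X, model$weights, model$config)$scores
  } else {
    cnn_forward_core(X, model$weights, model$config)$scores
  }
}

#' Train a network on a labelled stimulus set
#'
#' Minimises multinomial cross-entropy with minibatch stochastic gradient
#' descent and momentum. A held-out fraction is split off for per-epoch
#' accuracy logging. With `epochs = 0` the freshly initialised weights are
#' returned untouched (accuracy near chance). Deterministic given `seed`.
#'
#' @param model An untrained model from [new_model()].
#' @param dataset A list with `images` and `labels`
#'   (see [build_training_set()]).
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param optimizer `"adam"` (default; robust for the sparse activations of
#'   wide-field inputs) or `"sgd"` (plain momentum SGD).
#' @param lr Learning rate (default 1e-3 for adam; use ~0.05 for sgd).
#' @param momentum Momentum coefficient (sgd only).
#' @param val_fraction Held-out fraction for validation accuracy.
#' @param seed Seed for the split and shuffling.
#' @param verbose Print per-epoch progress.
#' @return The model with trained weights and a `log` data frame
#'   (epoch, train_loss, val_accuracy).
#' @export
train_network <- function(model, dataset, epochs = 2L, batch_size = 8L,
                          optimizer = c("adam", "sgd"), lr = 1e-3,
                          momentum = 0.9, val_fraction = 0.1,
                          seed = 1L, verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  images <- dataset$images
  labels <- as.integer(dataset$labels)
  stopifnot(length(images) == length(labels),
            max(labels) <= model$config$n_classes)
  n <- length(images)
  log_rows <- list()
  with_seed(seed, {
    n_val <- max(if (val_fraction > 0) 1L else 0L, round(val_fraction * n))
    idx <- sample(n)
    val_idx <- if (n_val > 0) idx[seq_len(n_val)] else integer(0)
    tr_idx <- setdiff(idx, val_idx)
    Xval <- if (n_val > 0) prep_inputs(model, images[val_idx]) else NULL
    vel <- rapply(model$weights, function(x) x * 0, how = "replace")
    m1 <- vel; m2 <- vel
    step <- 0L
    upd <- function(w, g, v, mm1, mm2) {
      if (optimizer == "adam") {
        mm1 <- 0.9 * mm1 + 0.1 * g
        mm2 <- 0.999 * mm2 + 0.001 * g * g
        mh <- mm1 / (1 - 0.9^step)
        vh <- mm2 / (1 - 0.999^step)
        list(w = w - lr * mh / (sqrt(vh) + 1e-8), v = v, m1 = mm1, m2 = mm2)
      } else {
        v <- momentum * v - lr * g
        list(w = w + v, v = v, m1 = mm1, m2 = mm2)
      }
    }
    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      losses <- numeric(0)
      for (start in seq(1L, length(ord), by = batch_size)) {
        bi <- ord[start:min(start + batch_size - 1L, length(ord))]
        X <- prep_inputs(model, images[bi])
        fb <- forward_backward(model, X, labels[bi])
        if (!is.finite(fb$loss)) {
          stop("training diverged (non-finite loss)", call. = FALSE)
        }
        losses <- c(losses, fb$loss)
        step <- step + 1L
        for (i in seq_along(model$weights$conv)) {
          for (pn in c("W", "b")) {
            gn <- if (pn == "W") "dW" else "db"
            u <- upd(model$weights$conv[[i]][[pn]], fb$grads$conv[[i]][[gn]],
                     vel$conv[[i]][[pn]], m1$conv[[i]][[pn]],
                     m2$conv[[i]][[pn]])
            model$weights$conv[[i]][[pn]] <- u$w
            vel$conv[[i]][[pn]] <- u$v
            m1$conv[[i]][[pn]] <- u$m1
            m2$conv[[i]][[pn]] <- u$m2
          }
        }
        for (pn in c("W", "b")) {
          gn <- if (pn == "W") "dW" else "db"
          u <- upd(model$weights$fc[[pn]], fb$grads$fc[[gn]], vel$fc[[pn]],
                   m1$fc[[pn]], m2$fc[[pn]])
          model$weights$fc[[pn]] <- u$w
          vel$fc[[pn]] <- u$v
          m1$fc[[pn]] <- u$m1
          m2$fc[[pn]] <- u$m2
        }
      }
      val_acc <- NA_real_
      if (n_val > 0) {
        pred <- apply(predict_scores(model, Xval), 2L, which.max)
        val_acc <- mean(pred == labels[val_idx])
      }
      log_rows[[ep]] <- data.frame(epoch = ep, train_loss = mean(losses),
                                   val_accuracy = val_acc)
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f, val acc %.3f",
                        ep, mean(losses), val_acc))
      }
    }
  })
  model$trained <- model$trained || epochs > 0L
  new_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(epoch = integer(0), train_loss = numeric(0),
               val_accuracy = numeric(0))
  if (!is.null(model$log) && nrow(model$log)) {
    # continued training: append with a running epoch counter
    new_log$epoch <- new_log$epoch + max(model$log$epoch)
    new_log <- rbind(model$log, new_log)
  }
  model$log <- new_log
  model
}
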