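# Convolution / pooling primitives (im2col + BLAS GEMM), pure R.
#
# Activations are 4-D arrays [H, W, C, B] (column-major). Convolutions use
# zero padding; spatial max-pooling uses ceil-mode windows clamped by -Inf
# padding on the bottom/right. Backward passes: conv weight gradients via
# im2col GEMM, conv input gradients via the transposed convolution (stride-1
# layers) or an explicit scatter-add fallback, pool gradients via argmax
# scatter. Gradients are verified against numerical differentiation in the
# test suite.

.plan_cache <- new.env(parent = emptyenv())

conv_out_dim <- function(n, k, s, p) (n + 2L * p - k) %/% s + 1L

conv_plan <- function(H, W, C, k, s, p) {
  key <- paste("c", H, W, C, k, s, p, sep = "_")
  pl <- .plan_cache[[key]]
  if (!is.null(pl)) return(pl)
  Hp <- H + 2L * p; Wp <- W + 2L * p
  oh <- conv_out_dim(H, k, s, p); ow <- conv_out_dim(W, k, s, p)
  stopifnot(oh >= 1, ow >= 1)
  ii <- rep(seq_len(oh), times = ow); jj <- rep(seq_len(ow), each = oh)
  base <- (ii - 1L) * s + (jj - 1L) * s * Hp + 1L      # top-left linear index
  pr <- rep(seq_len(k), times = k * C)
  pc <- rep(rep(seq_len(k), each = k), times = C)
  chn <- rep(seq_len(C), each = k * k)
  off <- (chn - 1L) * Hp * Wp + (pc - 1L) * Hp + (pr - 1L)
  idx <- outer(base, off, `+`)                          # [oh*ow, k*k*C]
  storage.mode(idx) <- "integer"
  pl <- list(Hp = Hp, Wp = Wp, oh = oh, ow = ow, idx = idx,
             H = H, W = W, C = C, k = k, s = s, p = p)
  .plan_cache[[key]] <- pl
  pl
}

pad_input <- function(X, p, value = 0) {
  # X: [H, W, C, B] -> matrix [Hp*Wp*C, B]
  d <- dim(X)
  if (p == 0L) { dim(X) <- c(d[1L] * d[2L] * d[3L], d[4L]); return(X) }
  Hp <- d[1L] + 2L * p; Wp <- d[2L] + 2L * p
  Xp <- array(value, c(Hp, Wp, d[3L], d[4L]))
  Xp[(p + 1L):(p + d[1L]), (p + 1L):(p + d[2L]), , ] <- X
  dim(Xp) <- c(Hp * Wp * d[3L], d[4L])
  Xp
}

conv_forward <- function(X, Wm, bias, k, s, p, keep_cache = FALSE) {
  d <- dim(X); B <- d[4L]
  pl <- conv_plan(d[1L], d[2L], d[3L], k, s, p)
  Xp <- pad_input(X, p)
  nf <- ncol(Wm)
  Y <- cpp_conv_forward(Xp, pl$idx, Wm, bias)
  dim(Y) <- c(pl$oh, pl$ow, nf, B)
  list(out = Y,
       cache = if (keep_cache) list(Xp = Xp, plan = pl, Wm = Wm) else NULL)
}

# transposed-conv weight matrix: [k*k*F, C] with flipped spatial taps
conv_weight_transpose <- function(Wm, k, C) {
  nf <- ncol(Wm)
  Wa <- array(Wm, c(k, k, C, nf))
  Wa <- Wa[k:1, k:1, , , drop = FALSE]
  Wa <- aperm(Wa, c(1L, 2L, 4L, 3L))
  dim(Wa) <- c(k * k * nf, C)
  Wa
}

conv_backward <- function(dY, cache, need_dx = TRUE) {
  pl <- cache$plan
  d <- dim(dY); nf <- d[3L]; B <- d[4L]
  ohw <- pl$oh * pl$ow
  dim(dY) <- c(ohw * nf, B)
  g <- cpp_conv_dw(cache$Xp, pl$idx, dY, nf)
  dW <- g$dW
  db <- as.numeric(g$db)
  dX <- NULL
  if (need_dx) {
    dim(dY) <- c(pl$oh, pl$ow, nf, B)
    if (pl$s == 1L) {
      Wt <- conv_weight_transpose(cache$Wm, pl$k, pl$C)
      dX <- conv_forward(dY, Wt, numeric(ncol(Wt)),
                         k = pl$k, s = 1L, p = pl$k - 1L - pl$p)$out
    } else {
      dX <- conv_scatter_dx(dY, cache)
    }
  }
  list(dW = dW, db = db, dX = dX)
}

# generic col2im scatter (any stride); used where the transposed-conv route
# does not apply
conv_scatter_dx <- function(dY, cache) {
  pl <- cache$plan
  d <- dim(dY); nf <- d[3L]; B <- d[4L]
  ohw <- pl$oh * pl$ow
  npad <- pl$Hp * pl$Wp * pl$C
  dXp <- matrix(0, npad, B)
  Wt <- t(cache$Wm)
  dim(dY) <- c(ohw * nf, B)
  for (b in seq_len(B)) {
    dcol <- matrix(dY[, b], ohw, nf) %*% Wt     # [ohw, k*k*C]
    dXp[, b] <- cpp_scatter_add(dcol, pl$idx, npad)
  }
  dim(dXp) <- c(pl$Hp, pl$Wp, pl$C, B)
  p <- pl$p
  dXp[(p + 1L):(p + pl$H), (p + 1L):(p + pl$W), , , drop = FALSE]
}

pool_plan <- function(H, W, k, s) {
  key <- paste("p", H, W, k, s, sep = "_")
  pl <- .plan_cache[[key]]
  if (!is.null(pl)) return(pl)
  oh <- max(1L, as.integer(ceiling((H - k) / s)) + 1L)
  ow <- max(1L, as.integer(ceiling((W - k) / s)) + 1L)
  Hp <- max(H, (oh - 1L) * s + k); Wp <- max(W, (ow - 1L) * s + k)
  ii <- rep(seq_len(oh), times = ow); jj <- rep(seq_len(ow), each = oh)
  base <- (ii - 1L) * s + (jj - 1L) * s * Hp + 1L
  pr <- rep(seq_len(k), times = k)
  pc <- rep(seq_len(k), each = k)
  off <- (pc - 1L) * Hp + (pr - 1L)
  idx <- outer(base, off, `+`)
  storage.mode(idx) <- "integer"
  pl <- list(Hp = Hp, Wp = Wp, oh = oh, ow = ow, idx = idx, idxt = t(idx),
             H = H, W = W, k = k, s = s)
  .plan_cache[[key]] <- pl
  pl
}

pool_forward <- function(X, k, s, keep_cache = FALSE) {
  d <- dim(X); H <- d[1L]; W <- d[2L]; CB <- d[3L] * d[4L]
  pl <- pool_plan(H, W, k, s)
  if (pl$Hp > H || pl$Wp > W) {
    Xp <- array(-Inf, c(pl$Hp, pl$Wp, CB))
    dim(X) <- c(H, W, CB)
    Xp[1:H, 1:W, ] <- X
    dim(Xp) <- c(pl$Hp * pl$Wp, CB)
  } else {
    Xp <- X
    dim(Xp) <- c(pl$Hp * pl$Wp, CB)
  }
  pm <- cpp_pool_max(Xp, pl$idxt)
  out <- pm$out
  amax <- pm$amax
  dim(out) <- c(pl$oh, pl$ow, d[3L], d[4L])
  list(out = out,
       cache = if (keep_cache) list(plan = pl, amax = amax,
                                    C = d[3L], B = d[4L]) else NULL)
}

pool_backward <- function(dY, cache) {
  pl <- cache$plan
  CB <- cache$C * cache$B
  ohw <- pl$oh * pl$ow
  dim(dY) <- c(ohw, CB)
  dXp <- cpp_pool_scatter(dY, cache$amax, pl$idxt, pl$Hp * pl$Wp)
  dim(dXp) <- c(pl$Hp, pl$Wp, CB)
  dX <- dXp[seq_len(pl$H), seq_len(pl$W), , drop = FALSE]
  dim(dX) <- c(pl$H, pl$W, cache$C, cache$B)
  dX
}

# --- layer stack ------------------------------------------------------------

# arch: list of layers, each list(k, s, p, f, pool_k, pool_s); conv -> ReLU ->
# max-pool per layer. Weights: list(conv = list(list(W, b), ...)).

stack_dims <- function(grid, arch, c_in = 1L) {
  H <- grid; C <- c_in
  dims <- list()
  for (i in seq_along(arch)) {
    l <- arch[[i]]
    hc <- conv_out_dim(H, l$k, l$s, l$p)
    hp <- max(1L, as.integer(ceiling((hc - l$pool_k) / l$pool_s)) + 1L)
    dims[[i]] <- c(conv = hc, pool = hp, filters = l$f)
    H <- hp; C <- l$f
  }
  list(per_layer = dims, out_side = H, out_filters = C,
       feature_len = H * H * C)
}

init_stack_weights <- function(arch, c_in = 1L) {
  C <- c_in
  conv <- vector("list", length(arch))
  for (i in seq_along(arch)) {
    l <- arch[[i]]
    fan_in <- l$k * l$k * C
    conv[[i]] <- list(W = matrix(stats::rnorm(fan_in * l$f,
                                              sd = sqrt(2 / fan_in)),
                                 fan_in, l$f),
                      b = numeric(l$f))
    C <- l$f
  }
  conv
}

stack_forward <- function(X, conv_weights, arch, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(arch)) else NULL
  for (i in seq_along(arch)) {
    l <- arch[[i]]
    cf <- conv_forward(X, conv_weights[[i]]$W, conv_weights[[i]]$b,
                       l$k, l$s, l$p, keep_cache = keep_cache)
    A <- cf$out
    cpp_relu_inplace(A)
    pf <- pool_forward(A, l$pool_k, l$pool_s, keep_cache = keep_cache)
    if (keep_cache) {
      # post-ReLU activations double as the rectifier mask
      caches[[i]] <- list(conv = cf$cache, act = A, pool = pf$cache)
    }
    X <- pf$out
  }
  list(out = X, caches = caches)
}

stack_backward <- function(dOut, caches, arch, need_dx_input = FALSE) {
  grads <- vector("list", length(arch))
  dX <- dOut
  for (i in rev(seq_along(arch))) {
    dA <- pool_backward(dX, caches[[i]]$pool)
    cpp_relu_backward(dA, caches[[i]]$act)
    need <- i > 1L || need_dx_input
    cb <- conv_backward(dA, caches[[i]]$conv, need_dx = need)
    grads[[i]] <- list(dW = cb$dW, db = cb$db)
    dX <- cb$dX
  }
  list(grads = grads, dX = dX)
}

fc_forward <- function(feat, W, b) crossprod(W, feat) + b

softmax_xent <- function(scores, labels) {
  # scores: [n_classes, B]; labels: integer vector in 1..n_classes
  B <- ncol(scores)
  m <- apply(scores, 2L, max)
  E <- exp(sweep(scores, 2L, m))
  P <- sweep(E, 2L, colSums(E), "/")
  sel <- cbind(labels, seq_len(B))
  loss <- -mean(log(pmax(P[sel], 1e-12)))
  dS <- P
  dS[sel] <- dS[sel] - 1
  list(loss = loss, probs = P, dscores = dS / B)
}
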