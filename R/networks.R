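# Network architectures.
#
# Both models share the same four-layer convolutional stack followed by one
# fully connected layer: layer 1 is an 11x11 convolution with stride 4 and
# 5x5 spatial max-pooling with stride 2; layers 2-4 are 5x5 convolutions with
# stride 1 and 5x5 pooling with stride 2. The scale-channel model (ENN)
# applies the *same* weights to every channel of the centred-crop pyramid and
# max-pools element-wise over channels at the last layer before the
# classifier; the single-scale control (CNN) sees the whole field once, at
# the resolution of the pyramid's 5th channel (its mid-resolution).

build_arch <- function(n_filters) {
  stopifnot(length(n_filters) == 4L, all(n_filters >= 1))
  ks <- c(11L, 5L, 5L, 5L)
  ss <- c(4L, 1L, 1L, 1L)
  lapply(1:4, function(i) {
    list(k = ks[i], s = ss[i], p = ks[i] %/% 2L, f = as.integer(n_filters[i]),
         pool_k = 5L, pool_s = 2L)
  })
}

#' Scale-channel network (ENN) configuration
#'
#' @param pyramid A [pyramid_spec()]; its common grid is the per-channel
#'   input side.
#' @param calibration A [field_calibration()].
#' @param n_filters Four filter counts, one per convolutional layer. The
#'   layer kernel/stride table is fixed (see package docs); filter counts are
#'   a free capacity choice.
#' @param n_classes Classes of the supervised training task.
#' @param seed Seed for weight initialisation.
#' @return An `enn_config` with derived shape information (`feature_len` is
#'   the length of the per-channel feature vector before scale pooling).
#' @export
enn_config <- function(pyramid = pyramid_spec(),
                       calibration = field_calibration(),
                       n_filters = c(32, 32, 64, 64),
                       n_classes = 10L, seed = 1L) {
  arch <- build_arch(n_filters)
  dims <- stack_dims(pyramid$common_grid, arch)
  structure(list(pyramid = pyramid, calibration = calibration,
                 arch = arch, n_filters = as.integer(n_filters),
                 n_classes = as.integer(n_classes), seed = as.integer(seed),
                 feature_len = dims$feature_len, dims = dims,
                 scale_pool = "max"),
            class = "enn_config")
}

#' Single-scale control network (CNN) configuration
#'
#' Same layers and training regime as the scale-channel model, but a single
#' input channel: the full simulated visual field resampled to the resolution
#' of pyramid channel `input_channel` (default the 5th, the mid-resolution).
#'
#' @inheritParams enn_config
#' @param input_channel 1-based pyramid channel whose resolution defines the
#'   input raster.
#' @return A `cnn_config`; `input_px` is the input raster side.
#' @export
cnn_config <- function(pyramid = pyramid_spec(),
                       calibration = field_calibration(),
                       n_filters = c(32, 32, 64, 64),
                       n_classes = 10L, input_channel = 5L, seed = 1L) {
  stopifnot(input_channel >= 1, input_channel <= pyramid$n_channels)
  res <- channel_resolution(pyramid, input_channel, calibration)
  input_px <- as.integer(round(calibration$field_pixels *
                                 res / calibration$pixels_per_degree))
  arch <- build_arch(n_filters)
  dims <- stack_dims(input_px, arch)
  structure(list(pyramid = pyramid, calibration = calibration,
                 arch = arch, n_filters = as.integer(n_filters),
                 n_classes = as.integer(n_classes),
                 input_channel = as.integer(input_channel),
                 input_px = input_px, input_resolution = res,
                 seed = as.integer(seed),
                 feature_len = dims$feature_len, dims = dims),
            class = "cnn_config")
}

init_weights <- function(config) {
  with_seed(config$seed, {
    conv <- init_stack_weights(config$arch)
    len <- config$feature_len
    fc <- list(W = matrix(stats::rnorm(len * config$n_classes,
                                       sd = sqrt(2 / len)),
                          len, config$n_classes),
               b = numeric(config$n_classes))
    list(conv = conv, fc = fc)
  })
}

#' Instantiate a model with freshly initialised weights
#'
#' @param config An [enn_config()] or [cnn_config()].
#' @return A model object (`enn_model` / `cnn_model`) holding the config and
#'   He-initialised weights; train with [train_network()].
#' @export
new_model <- function(config) {
  cls <- if (inherits(config, "enn_config")) "enn_model" else "cnn_model"
  structure(list(config = config, weights = init_weights(config),
                 trained = FALSE, log = NULL),
            class = cls)
}

#' @export
print.enn_model <- function(x, ...) {
  cat(sprintf("<enn_model> %d scale channels, grid %d, filters %s, %s\n",
              x$config$pyramid$n_channels, x$config$pyramid$common_grid,
              paste(x$config$n_filters, collapse = "-"),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> input %d px (%.1f px/deg), filters %s, %s\n",
              x$config$input_px, x$config$input_resolution,
              paste(x$config$n_filters, collapse = "-"),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# --- forward passes ---------------------------------------------------------

# pyramids: a crop_pyramid, or an array [g, g, n_channels, B]
as_pyramid_array <- function(pyramids) {
  if (inherits(pyramids, "crop_pyramid")) {
    a <- pyramids$channels
    dim(a) <- c(dim(a), 1L)
    return(a)
  }
  stopifnot(length(dim(pyramids)) == 4L)
  pyramids
}

# batched core: returns bank [len, nch, B], pooled [len, B], scores
# [n_classes, B]; optionally caches for backprop
enn_forward_core <- function(parr, weights, config, keep_cache = FALSE) {
  d <- dim(parr); g <- d[1L]; nch <- d[3L]; B <- d[4L]
  X <- parr
  dim(X) <- c(g, g, 1L, nch * B)
  sf <- stack_forward(X, weights$conv, config$arch, keep_cache = keep_cache)
  len <- config$feature_len
  bank <- sf$out
  dim(bank) <- c(len, nch, B)
  pooled <- bank[, 1L, , drop = FALSE]
  dim(pooled) <- c(len, B)
  amax <- matrix(1L, len, B)
  if (nch > 1L) {
    for (k in 2:nch) {
      v <- bank[, k, ]
      dim(v) <- c(len, B)
      upd <- v > pooled
      if (any(upd)) { amax[upd] <- k; pooled[upd] <- v[upd] }
    }
  }
  scores <- fc_forward(pooled, weights$fc$W, weights$fc$b)
  list(bank = bank, pooled = pooled, scores = scores, amax = amax,
       caches = sf$caches, nch = nch, B = B)
}

#' Forward pass of the scale-channel network
#'
#' Every pyramid channel is processed by the identical four-layer stack
#' (weight sharing across scales); the per-channel flattened features of the
#' last conv+pool layer form the feature bank (the multi-resolution template
#' stored at learning time), their element-wise maximum over channels is the
#' scale-pooled feature, and the fully connected layer maps the pooled
#' feature to class scores.
#'
#' @param pyramid A `crop_pyramid` (see [sample_pyramid()]).
#' @param model An `enn_model`.
#' @return List with `bank` (`feature_len` x `n_channels` matrix), `pooled`
#'   (vector), `scores` (vector).
#' @export
enn_forward <- function(pyramid, model) {
  stopifnot(inherits(model, "enn_model"))
  parr <- as_pyramid_array(pyramid)
  if (dim(parr)[1L] != model$config$pyramid$common_grid) {
    stop("pyramid grid does not match the model configuration", call. = FALSE)
  }
  r <- enn_forward_core(parr, model$weights, model$config)
  list(bank = matrix(r$bank[, , 1L], nrow = model$config$feature_len),
       pooled = r$pooled[, 1L], scores = r$scores[, 1L])
}

#' Resample a visual field to the control network's input raster
#'
#' Pads the field to the full calibrated span (background fills in) and
#' box-average resamples it to `config$input_px`.
#'
#' @param image A `visual_field` in network polarity (see [network_input()]).
#' @param config A [cnn_config()].
#' @return `input_px` x `input_px` matrix.
#' @export
cnn_input <- function(image, config) {
  m <- config$input_px
  Nf <- config$calibration$field_pixels
  ctr <- image$n / 2
  e <- ctr - Nf / 2 + Nf * (0:m) / m
  field_boxgrid(image, e, e)
}

cnn_forward_core <- function(X, weights, config, keep_cache = FALSE) {
  sf <- stack_forward(X, weights$conv, config$arch, keep_cache = keep_cache)
  feat <- sf$out
  dim(feat) <- c(config$feature_len, dim(X)[4L])
  scores <- fc_forward(feat, weights$fc$W, weights$fc$b)
  list(feature = feat, scores = scores, caches = sf$caches)
}

#' Forward pass of the single-scale control network
#'
#' @param image A `visual_field` in network polarity, or a pre-resampled
#'   input matrix of side `config$input_px`.
#' @param model A `cnn_model`.
#' @return List with `feature` (flattened last conv+pool layer, the vector
#'   used for similarity) and `scores`.
#' @export
cnn_forward <- function(image, model) {
  stopifnot(inherits(model, "cnn_model"))
  X <- if (inherits(image, "visual_field")) cnn_input(image, model$config)
       else image
  if (nrow(X) != model$config$input_px) {
    stop("input raster does not match the model configuration", call. = FALSE)
  }
  dim(X) <- c(nrow(X), ncol(X), 1L, 1L)
  r <- cnn_forward_core(X, model$weights, model$config)
  list(feature = r$feature[, 1L], scores = r$scores[, 1L])
}

# --- shared feature-extraction interface ------------------------------------

# returns list(bank = matrix [len, n_templates], pooled = vector); for the
# CNN the bank degenerates to the single feature vector.
model_features <- function(model, image) UseMethod("model_features")

#' @export
model_features.enn_model <- function(model, image) {
  p <- sample_pyramid(network_input(image), model$config$pyramid)
  f <- enn_forward(p, model)
  list(bank = f$bank, pooled = f$pooled)
}

#' @export
model_features.cnn_model <- function(model, image) {
  f <- cnn_forward(network_input(image), model)
  list(bank = matrix(f$feature, ncol = 1L), pooled = f$feature)
}
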