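make_tiny_pyramid_array <- function(seed = 1, nch = 4L, g = 24L, B = 1L) {
  with_seed <- foveanet:::with_seed
  with_seed(seed, array(abs(rnorm(g * g * nch * B, sd = 0.3)),
                        c(g, g, nch, B)))
}

test_that("shared weights: per-channel forward equals the batched pass", {
  cfg <- tiny_enn_config()
  m <- new_model(cfg)
  parr <- make_tiny_pyramid_array()
  full <- foveanet:::enn_forward_core(parr, m$weights, cfg)
  for (k in 1:4) {
    one <- parr[, , k, 1, drop = FALSE]
    dim(one) <- c(24L, 24L, 1L, 1L)
    sf <- foveanet:::stack_forward(one, m$weights$conv, cfg$arch)
    expect_equal(as.numeric(sf$out), full$bank[, k, 1], tolerance = 1e-12)
  }
})

test_that("blank pyramid gives identical channels and pooled equals any one", {
  cfg <- tiny_enn_config()
  m <- new_model(cfg)
  calib <- tiny_calib()
  p <- sample_pyramid(network_input(blank_field(
    field_calibration(48, field_span = 2))), cfg$pyramid)
  f <- enn_forward(p, m)
  for (k in 2:4) expect_equal(f$bank[, k], f$bank[, 1], tolerance = 1e-12)
  expect_equal(f$pooled, f$bank[, 1], tolerance = 1e-12)
})

test_that("scale pooling is channel-symmetric and dominates every channel", {
  cfg <- tiny_enn_config()
  m <- new_model(cfg)
  parr <- make_tiny_pyramid_array(seed = 4)
  f <- foveanet:::enn_forward_core(parr, m$weights, cfg)
  perm <- parr[, , c(3, 1, 4, 2), , drop = FALSE]
  fp <- foveanet:::enn_forward_core(perm, m$weights, cfg)
  expect_equal(fp$pooled, f$pooled, tolerance = 1e-12)
  bank <- f$bank[, , 1]
  pooled <- f$pooled[, 1]
  for (k in 1:4) expect_true(all(pooled >= bank[, k] - 1e-12))
  expect_true(all(abs(apply(bank, 1, max) - pooled) < 1e-12))
})

test_that("control network input geometry follows the mid-resolution channel", {
  cfg <- tiny_cnn_config()
  res <- channel_resolution(tiny_pyramid(), 3L, tiny_calib())
  expect_equal(cfg$input_resolution, res)
  expect_equal(cfg$input_px,
               round(tiny_calib()$field_pixels * res / 48))
  m <- new_model(cfg)
  pairs <- make_novel_pairs(2, seed = 6)
  rc <- field_calibration(48, field_span = 2)
  img <- render_stimulus(stimulus_spec("g01", 30), pairs, rc)
  f1 <- cnn_forward(network_input(img), m)
  f2 <- cnn_forward(network_input(img), m)
  expect_identical(f1$feature, f2$feature)
  expect_length(f1$feature, cfg$feature_len)
  expect_error(cnn_config(tiny_pyramid(), tiny_calib(),
                          input_channel = 9L), "input_channel")
})

test_that("pooled features are more scale-tolerant within than across glyphs", {
  # architectural scale tolerance: a centred glyph grown by the pyramid's
  # growth factor keeps a higher pooled-feature correlation with itself than
  # with a different glyph at the original size
  cfg <- enn_config(pyramid_spec(6, 1.5, 40, 40), field_calibration(80),
                    n_filters = c(6, 6, 8, 8), n_classes = 3, seed = 7)
  m <- new_model(cfg)
  pairs <- make_novel_pairs(4, seed = 21)
  rc <- field_calibration(80, field_span = 8)
  feat <- function(id, size) {
    img <- render_stimulus(stimulus_spec(id, size), pairs, rc)
    enn_forward(sample_pyramid(network_input(img), cfg$pyramid), m)$pooled
  }
  within <- vapply(target_ids(pairs), function(id) {
    pearson_cor(feat(id, 40), feat(id, 60))
  }, numeric(1))
  base <- feat("g01", 40)
  across <- vapply(c("g02", "g03", "g04"), function(id) {
    pearson_cor(base, feat(id, 40))
  }, numeric(1))
  expect_gt(mean(within), mean(across))
})

test_that("training improves over chance, is seeded, and zero epochs is inert", {
  classes <- make_glyph_classes(3, 8, seed = 31)
  calib <- field_calibration(80)
  pol <- augmentation_policy(c(24, 40), c(-0.3, 0.3), 2L, seed = 33)
  ds <- build_training_set(classes, pol, calib)
  cfg <- enn_config(pyramid_spec(6, 1.5, 40, 40), calib,
                    n_filters = c(6, 6, 8, 8), n_classes = 3, seed = 2)
  m0 <- new_model(cfg)
  m_zero <- train_network(m0, ds, epochs = 0L, seed = 1)
  expect_false(m_zero$trained)
  expect_identical(m_zero$weights, m0$weights)
  m1 <- train_network(m0, ds, epochs = 25L, lr = 2e-3, seed = 1)
  expect_true(m1$trained)
  expect_equal(nrow(m1$log), 25L)
  expect_gt(max(m1$log$val_accuracy), 1 / 3)
  expect_lt(m1$log$train_loss[25], m1$log$train_loss[1])
  m2 <- train_network(m0, ds, epochs = 25L, lr = 2e-3, seed = 1)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$weights, m2$weights)
  m3 <- train_network(m0, ds, epochs = 1L, lr = 2e-3, seed = 99)
  expect_false(identical(m1$weights$conv[[1]]$W, m3$weights$conv[[1]]$W))
})
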