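# Micro experiment configuration: tiny pyramid and filters, random-init
# models (zero training epochs), so the drivers run in seconds. Training
# quality is exercised in the acceptance suite.
micro_config <- function() {
  experiment_config(
    "desk",
    calibration = field_calibration(48),
    pyramid = pyramid_spec(3L, 1.5, 24L, 24L),
    n_filters = c(4, 4, 6, 6),
    n_classes = 3L, n_items = 2L,
    train_policy = list(size_range = c(24, 40), ecc_range = c(-0.5, 0.5),
                        samples_per_item = 1L),
    epochs = 0L, enn_extra_epochs = 0L, cnn_input_channel = 3L,
    n_pairs = 4L,
    scale_sizes = list(c(30, 30), c(30, 45)),
    translation_grid = list(`30` = c(0.2, 0.4), `60` = 0.4),
    corr_ecc = c(0, 0.3), corr_size = 30)
}

micro_models <- function(cfg, seed = 1) {
  list(enn = new_model(enn_config(cfg$pyramid, cfg$calibration,
                                  cfg$n_filters, cfg$n_classes,
                                  seed = seed + 17L)),
       cnn = new_model(cnn_config(cfg$pyramid, cfg$calibration,
                                  cfg$n_filters, cfg$n_classes,
                                  input_channel = 3L, seed = seed + 19L)),
       seed = seed)
}

test_that("experiment configs validate fields and placements", {
  expect_error(experiment_config("desk", nonsense = 1), "unknown config")
  expect_error(experiment_config(
    "desk", translation_grid = list(`30` = 50)),
    class = "foveanet_out_of_field")
  cfg <- micro_config()
  expect_s3_class(cfg, "experiment_config")
  expect_match(config_hash(cfg), "^[0-9a-f]+$")
  expect_false(config_hash(cfg) ==
                 config_hash(experiment_config("desk",
                                               calibration = field_calibration(48),
                                               pyramid = pyramid_spec(3L, 1.5, 24L, 24L),
                                               translation_grid = list(`30` = 1))))
})

test_that("identical config and seed reproduce the scale report bitwise", {
  cfg <- micro_config()
  models <- micro_models(cfg)
  r1 <- run_scale_experiment(cfg, models, seed = 1)
  r2 <- run_scale_experiment(cfg, models, seed = 1)
  expect_identical(r1, r2)
  expect_equal(attr(r1, "config_hash"), config_hash(cfg))
  expect_equal(attr(r1, "seed"), 1)
  # baseline rows are exact even for random-init models
  expect_true(all(r1$accuracy[r1$target_size == r1$test_size] == 1))
  d1 <- file.path(tempdir(), "exp_a"); d2 <- file.path(tempdir(), "exp_b")
  dir.create(d1, showWarnings = FALSE); dir.create(d2, showWarnings = FALSE)
  run_scale_experiment(cfg, models, seed = 1, out_dir = d1)
  run_scale_experiment(cfg, models, seed = 1, out_dir = d2)
  expect_identical(readLines(file.path(d1, "scale_experiment.csv")),
                   readLines(file.path(d2, "scale_experiment.csv")))
  meta <- jsonlite::read_json(file.path(d1, "scale_experiment_meta.json"))
  expect_equal(meta$config_hash, config_hash(cfg))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the translation driver builds consistent windows and tables", {
  cfg <- micro_config()
  models <- micro_models(cfg)
  tr <- suppressWarnings(
    run_translation_experiment(cfg, models, seed = 1,
                               cnn_regimes = "central", cnn_sizes = 30))
  rep <- tr$report
  # enn: 3 regimes x (2+1 and 1+1 nodes); cnn: central x (2+1 nodes)
  expect_equal(nrow(rep), 3 * 5 + 3)
  expect_true(all(rep$accuracy[rep$ecc == 0] == 1))
  expect_setequal(unique(rep$model), c("enn", "cnn"))
  w <- tr$windows$enn_central
  for (i in seq_len(nrow(w$grid))) {
    expect_equal(window_surface(w, w$grid$size[i], w$grid$ecc[i]),
                 w$grid$accuracy[i], tolerance = 1e-12)
  }
  expect_equal(tr$correlation$mean_correlation[1], 1)
  tr2 <- suppressWarnings(
    run_translation_experiment(cfg, models, seed = 1,
                               cnn_regimes = "central", cnn_sizes = 30))
  expect_identical(tr$report, tr2$report)
})

test_that("model training via the driver snapshots the matched budget", {
  cfg <- micro_config()
  models <- train_experiment_models(cfg, seed = 4)
  expect_s3_class(models$enn, "enn_model")
  expect_s3_class(models$enn_matched, "enn_model")
  expect_s3_class(models$cnn, "cnn_model")
  # zero-epoch micro profile: matched snapshot equals the final model
  expect_identical(models$enn$weights, models$enn_matched$weights)
})
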