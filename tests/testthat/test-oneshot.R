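tiny_models <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$m)) {
      cache$m <- list(enn = new_model(tiny_enn_config()),
                      cnn = new_model(tiny_cnn_config()))
    }
    cache$m
  }
})

test_that("condition specs infer and validate learning regimes", {
  expect_equal(condition_spec(30, 30, 0, 2)$regime, "central")
  expect_equal(condition_spec(30, 30, 2, 0)$regime, "peripheral")
  expect_equal(condition_spec(30, 30, 2, 2)$regime, "same")
  expect_equal(condition_spec(30, 30, 2, -2)$regime, "opposite")
  expect_equal(condition_spec(30)$regime, "baseline")
  expect_error(condition_spec(30, 30, 0, 2, regime = "peripheral"),
               "inconsistent")
})

test_that("bit-identical baseline presentations give accuracy exactly 1", {
  pairs <- make_novel_pairs(6, seed = 41)
  m <- tiny_models()
  for (model in m) {
    for (metric in c("symmetric", "asymmetric")) {
      r <- run_condition(condition_spec(30, 30, 0, 0, metric = metric),
                         pairs, model, tiny_calib())
      expect_identical(r$accuracy, 1)
      expect_equal(r$hit_rate, 1)
      expect_equal(r$fa_rate, 0)
      expect_true(all(r$similarities_same >= r$threshold))
      expect_equal(r$n_trials, 12L)
    }
  }
})

test_that("an indistinguishable distractor pins accuracy to one half", {
  pairs <- make_novel_pairs(4, seed = 43)
  degenerate <- pairs
  for (id in target_ids(degenerate)) {
    degenerate$glyphs[[distractor_of(degenerate, id)]] <-
      degenerate$glyphs[[id]]
  }
  r <- run_condition(condition_spec(30), degenerate, tiny_models()$enn,
                     tiny_calib())
  expect_equal(r$accuracy, 0.5)
})

test_that("a stimulus-blind stub model scores near chance", {
  # features independent of the stimulus: same and different trials draw
  # from one distribution, so the optimal threshold cannot do much
  stub <- structure(list(config = list(calibration = tiny_calib())),
                    class = "stub_model")
  assign("model_features.stub_model",
         function(model, image) {
           f <- rnorm(40)
           list(bank = matrix(f, ncol = 1), pooled = f)
         },
         envir = globalenv())
  withr::defer(rm("model_features.stub_model", envir = globalenv()))
  pairs <- make_novel_pairs(25, seed = 47)
  set.seed(7)
  # target and test placements must differ, otherwise the placement cache
  # (correctly) hands identical features to both presentations
  r <- run_condition(condition_spec(30, 45, 0, 1), pairs, stub, tiny_calib())
  expect_lt(r$accuracy, 0.72)   # in-sample optimum sits above 0.5 by chance
  expect_gte(r$accuracy, 0.5)
})

test_that("nonzero eccentricities are counterbalanced left/right", {
  pairs <- make_novel_pairs(3, seed = 49)
  r <- run_condition(condition_spec(30, 30, 0, 1), pairs,
                     tiny_models()$enn, tiny_calib())
  expect_equal(r$n_trials, 12L)   # 3 pairs x same/diff x 2 sides
  expect_length(r$similarities_same, 6L)
  r0 <- run_condition(condition_spec(30), pairs, tiny_models()$enn,
                      tiny_calib())
  expect_equal(r0$n_trials, 6L)   # no counterbalancing at fixation
})

test_that("feature caching does not change condition results", {
  pairs <- make_novel_pairs(3, seed = 53)
  m <- tiny_models()$enn
  cache <- new.env(parent = emptyenv())
  spec <- condition_spec(30, 30, 0, 1, metric = "asymmetric")
  r1 <- run_condition(spec, pairs, m, tiny_calib(), cache)
  r2 <- run_condition(spec, pairs, m, tiny_calib(), cache)
  r3 <- run_condition(spec, pairs, m, tiny_calib())
  expect_identical(r1$similarities_same, r2$similarities_same)
  expect_identical(r1$similarities_same, r3$similarities_same)
})

test_that("raw correlation is 1 at zero eccentricity and symmetric for one
          feature vector per image", {
  pairs <- make_novel_pairs(3, seed = 59)
  m <- tiny_models()
  tab <- correlation_vs_eccentricity(pairs, 30, c(0, 1), m$enn,
                                     metric = "asymmetric",
                                     calib = tiny_calib())
  expect_equal(tab$mean_correlation[1], 1)
  expect_lt(tab$mean_correlation[2], 1)
  # the control's symmetric metric cannot depend on presentation order
  cache <- new.env(parent = emptyenv())
  f0 <- foveanet:::placement_features(m$cnn, pairs, "g01", 30, 0,
                                      tiny_calib(), cache)
  f1 <- foveanet:::placement_features(m$cnn, pairs, "g01", 30, 1,
                                      tiny_calib(), cache)
  expect_identical(symmetric_similarity(f0, f1),
                   symmetric_similarity(f1, f0))
})
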