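test_that("arcmin conversion matches the 450 px/deg calibration", {
  calib <- field_calibration()
  expect_identical(arcmin_to_pixels(30, calib), 225L)
  expect_identical(arcmin_to_pixels(60, calib), 450L)
  expect_identical(arcmin_to_pixels(120, calib), 900L)
  expect_identical(arcmin_to_pixels(30, field_calibration(150)), 75L)
  expect_error(arcmin_to_pixels(0), "positive")
  expect_error(arcmin_to_pixels(-5), "positive")
})

test_that("field calibration invariants hold", {
  calib <- field_calibration()
  expect_equal(calib$field_pixels, round(calib$pixels_per_degree *
                                           calib$field_span))
  expect_equal(calib$field_pixels, 8650L)
  c2 <- field_calibration(150, field_pixels = 900)
  expect_equal(c2$field_span, 6)
  expect_error(field_calibration(100, field_span = -1), "positive")
})

test_that("rendered stimulus size round-trips through the bounding box", {
  pairs <- make_novel_pairs(2, seed = 5)
  calib <- field_calibration(150, field_span = 8)
  for (size in c(30, 77, 120)) {
    img <- render_stimulus(stimulus_spec("g01", size), pairs, calib)
    bb <- foveanet:::stimulus_bbox(img)
    target <- arcmin_to_pixels(size, calib)
    expect_lte(abs(max(bb$width, bb$height) - target), 2)
  }
})

test_that("rendering is deterministic and translation is an exact shift", {
  pairs <- make_novel_pairs(2, seed = 5)
  calib <- field_calibration(150, field_span = 6)
  a <- as.matrix(render_stimulus(stimulus_spec("g01", 30, 1), pairs, calib))
  b <- as.matrix(render_stimulus(stimulus_spec("g01", 30, 1), pairs, calib))
  expect_identical(a, b)
  center <- as.matrix(render_stimulus(stimulus_spec("g01", 30, 0), pairs,
                                      calib))
  shift <- round(1 * 150)
  n <- ncol(center)
  expect_identical(a[, (shift + 1):n], center[, 1:(n - shift)])
  # mirrored eccentricities are mirror translations of each other
  l <- as.matrix(render_stimulus(stimulus_spec("g01", 30, -1), pairs, calib))
  expect_identical(l[, 1:(n - shift)], center[, (shift + 1):n])
})

test_that("stimuli exceeding the field raise an out-of-field error", {
  pairs <- make_novel_pairs(1, seed = 1)
  calib <- field_calibration(150, field_span = 4)
  expect_error(render_stimulus(stimulus_spec("g01", 30, 3), pairs, calib),
               class = "foveanet_out_of_field")
  expect_error(render_stimulus(stimulus_spec("g01", 600, 0), pairs, calib),
               class = "foveanet_out_of_field")
})

test_that("sparse and dense renderings are the same image", {
  pairs <- make_novel_pairs(1, seed = 9)
  calib <- field_calibration(150, field_span = 5)
  sp <- render_stimulus(stimulus_spec("g01", 45, 0.7), pairs, calib,
                        sparse = TRUE)
  de <- render_stimulus(stimulus_spec("g01", 45, 0.7), pairs, calib)
  expect_identical(as.matrix(sp), as.matrix(de))
})

test_that("network polarity inverts dark-on-light to stimulus-positive", {
  pairs <- make_novel_pairs(1, seed = 3)
  calib <- field_calibration(150, field_span = 4)
  img <- render_stimulus(stimulus_spec("g01", 30), pairs, calib)
  ni <- network_input(img)
  expect_equal(ni$background, 0)
  expect_identical(as.matrix(ni), 1 - as.matrix(img))
  expect_identical(as.matrix(network_input(ni)), as.matrix(ni))
})

test_that("novel pair generation is seeded, distinct, and properly paired", {
  g <- make_novel_pairs(27, seed = 0)
  expect_length(g$glyphs, 54)
  expect_length(g$pairing, 27)
  expect_false(any(names(g$pairing) == unname(g$pairing)))
  # all rasters pairwise distinct
  keys <- vapply(g$glyphs, function(m) paste(round(m, 6), collapse = ","), "")
  expect_equal(anyDuplicated(keys), 0L)
  g2 <- make_novel_pairs(27, seed = 0)
  expect_identical(g$glyphs, g2$glyphs)
  g3 <- make_novel_pairs(5, seed = 1)
  g4 <- make_novel_pairs(5, seed = 0)
  expect_false(identical(g3$glyphs[["g01"]], g4$glyphs[["g01"]]))
  expect_error(distractor_of(g, "nope"), "no distractor")
})

test_that("training-set generation preserves counts, labels, and seeds", {
  classes <- make_glyph_classes(3, 4, seed = 7)
  expect_length(classes$glyphs, 12)
  expect_equal(sort(unique(classes$labels)), 1:3)
  calib <- field_calibration(96)
  pol <- augmentation_policy(c(20, 60), c(-1, 1), 2L, seed = 11)
  ds <- build_training_set(classes, pol, calib)
  expect_length(ds$images, 24)
  expect_equal(as.integer(table(ds$labels)), rep(8L, 3))
  ds2 <- build_training_set(classes, pol, calib)
  expect_identical(ds$specs, ds2$specs)
  # degenerate policy: single placement repeated
  pol0 <- augmentation_policy(c(30, 30), c(0, 0), 2L, seed = 11)
  ds0 <- build_training_set(classes, pol0, calib)
  expect_true(all(ds0$specs$size == 30 & ds0$specs$eccentricity == 0))
  # a policy that can leave the field fails up front
  wild <- augmentation_policy(c(20, 60), c(-80, 80), 1L, seed = 1)
  expect_error(build_training_set(classes, wild, calib),
               class = "foveanet_out_of_field")
  expect_error(build_training_set(make_novel_pairs(2, seed = 1), pol, calib),
               "labels")
})

test_that("resampling is exact on constants and preserves mass on average", {
  M <- matrix(runif(64 * 64), 64, 64)
  down <- resample_image(M, 16)
  expect_equal(mean(down), mean(M), tolerance = 1e-12)
  expect_equal(resample_image(matrix(0.3, 10, 10), 33), matrix(0.3, 33, 33))
  up <- resample_image(M, 128)
  expect_equal(dim(up), c(128L, 128L))
  expect_equal(mean(up), mean(M), tolerance = 1e-2)
})
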