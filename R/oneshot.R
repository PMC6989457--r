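# One-shot same/different evaluation protocol.

#' Specification of one same/different condition
#'
#' A condition fixes the target (learned) and test presentations: sizes in
#' arcmin and signed eccentricities in degrees. The learning regime follows
#' the eccentricities: central (0 -> D), peripheral (D -> 0), same (D -> D),
#' opposite (D -> -D), or baseline (0 -> 0).
#'
#' @param target_size,test_size Letter sizes in arcmin.
#' @param target_ecc,test_ecc Signed eccentricities in degrees.
#' @param metric `"symmetric"` (pooled features both sides) or `"asymmetric"`
#'   (per-channel templates for the target, pooled test).
#' @param regime Optional regime label; inferred from the eccentricities when
#'   missing, validated against them when given.
#' @return A `condition_spec`.
#' @export
condition_spec <- function(target_size, test_size = target_size,
                           target_ecc = 0, test_ecc = 0,
                           metric = c("symmetric", "asymmetric"),
                           regime = NULL) {
  metric <- match.arg(metric)
  inferred <-
    if (target_ecc == 0 && test_ecc == 0) "baseline"
    else if (target_ecc == 0) "central"
    else if (test_ecc == 0) "peripheral"
    else if (target_ecc == test_ecc) "same"
    else if (target_ecc == -test_ecc) "opposite"
    else "other"
  if (is.null(regime)) regime <- inferred
  else if (regime != inferred) {
    stop(sprintf("regime '%s' inconsistent with eccentricities (%g -> %g)",
                 regime, target_ecc, test_ecc), call. = FALSE)
  }
  structure(list(target_size = target_size, test_size = test_size,
                 target_ecc = target_ecc, test_ecc = test_ecc,
                 metric = metric, regime = regime),
            class = "condition_spec")
}

# compact calibration: just big enough for the widest placement, same px/deg
compact_calibration <- function(calib, sizes, eccs, margin = 0.5) {
  span <- 2 * (max(abs(eccs)) + max(sizes) / 120 + margin)
  span <- min(span, calib$field_span)
  field_calibration(calib$pixels_per_degree, field_span = span)
}

# features for one placement, with optional memoisation across conditions
placement_features <- function(model, glyphs, glyph_id, size, ecc, calib,
                               cache = NULL) {
  key <- sprintf("%s|%g|%g", glyph_id, size, ecc)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  rc <- compact_calibration(calib, size, ecc)
  img <- render_stimulus(stimulus_spec(glyph_id, size, ecc), glyphs, rc,
                         sparse = TRUE)
  f <- model_features(model, img)
  if (!is.null(cache)) cache[[key]] <- f
  f
}

# extract features for a table of placements in minibatches, filling `cache`
# keyed by "glyph|size|ecc"; avoids per-image forward-pass overhead
ensure_features <- function(model, glyphs, plc, calib, cache, chunk = 8L) {
  keys <- sprintf("%s|%g|%g", plc$glyph_id, plc$size, plc$ecc)
  miss <- !duplicated(keys) &
    !vapply(keys, function(k) !is.null(cache[[k]]), logical(1))
  plc <- plc[miss, , drop = FALSE]
  keys <- keys[miss]
  if (nrow(plc) == 0L) return(invisible(NULL))
  cfg <- model$config
  is_enn <- inherits(model, "enn_model")
  if (!is_enn && !inherits(model, "cnn_model")) {
    # other model classes (e.g. test stubs) go through model_features()
    for (i in seq_len(nrow(plc))) {
      rc <- compact_calibration(calib, plc$size[i], plc$ecc[i])
      img <- render_stimulus(stimulus_spec(plc$glyph_id[i], plc$size[i],
                                           plc$ecc[i]), glyphs, rc,
                             sparse = TRUE)
      cache[[keys[i]]] <- model_features(model, img)
    }
    return(invisible(NULL))
  }
  for (start in seq(1L, nrow(plc), by = chunk)) {
    sel <- start:min(start + chunk - 1L, nrow(plc))
    imgs <- lapply(sel, function(i) {
      rc <- compact_calibration(calib, plc$size[i], plc$ecc[i])
      render_stimulus(stimulus_spec(plc$glyph_id[i], plc$size[i],
                                    plc$ecc[i]),
                      glyphs, rc, sparse = TRUE)
    })
    if (is_enn) {
      X <- prep_inputs_enn(imgs, cfg)
      r <- enn_forward_core(X, model$weights, cfg)
      for (j in seq_along(sel)) {
        cache[[keys[sel[j]]]] <- list(
          bank = matrix(r$bank[, , j], nrow = cfg$feature_len),
          pooled = r$pooled[, j])
      }
    } else {
      X <- prep_inputs_cnn(imgs, cfg)
      r <- cnn_forward_core(X, model$weights, cfg)
      for (j in seq_along(sel)) {
        f <- r$feature[, j]
        cache[[keys[sel[j]]]] <- list(bank = matrix(f, ncol = 1L), pooled = f)
      }
    }
  }
  invisible(NULL)
}

condition_similarity <- function(metric, target_feat, test_feat) {
  if (metric == "asymmetric") {
    asymmetric_similarity(target_feat, test_feat)$similarity
  } else {
    symmetric_similarity(target_feat, test_feat)
  }
}

#' Run one same/different condition over a paired glyph set
#'
#' For every target/distractor pair the target is rendered at
#' (`target_size`, `target_ecc`) and the test at (`test_size`, `test_ecc`),
#' once as the same glyph and once as its paired distractor, giving balanced
#' same/different trials. Presentations at nonzero eccentricity are
#' counterbalanced over the left and right visual field (both placements
#' mirrored). Similarities are computed under the condition's metric, the
#' accuracy-maximising threshold is selected per condition, and d-prime is
#' derived from the implied hit/false-alarm rates.
#'
#' @param spec A [condition_spec()].
#' @param pairs A paired `glyph_set` with at least 2 pairs.
#' @param model A trained (or deliberately untrained) model.
#' @param calib Full-field [field_calibration()]; defaults to the model's.
#' @param cache Optional environment memoising placement features across
#'   conditions.
#' @return A `condition_result`: `accuracy`, `threshold`, `d_prime`,
#'   `hit_rate`, `fa_rate`, `similarities_same`, `similarities_diff`,
#'   `n_trials`, and the spec.
#' @export
run_condition <- function(spec, pairs, model,
                          calib = model$config$calibration, cache = NULL) {
  tids <- target_ids(pairs)
  if (length(tids) < 2L) stop("need at least 2 glyph pairs", call. = FALSE)
  sides <- if (spec$target_ecc != 0 || spec$test_ecc != 0) c(1, -1) else 1
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  dids <- vapply(tids, function(id) distractor_of(pairs, id), character(1))
  plc <- rbind(
    expand.grid(glyph_id = tids, size = spec$target_size,
                ecc = sides * spec$target_ecc, stringsAsFactors = FALSE),
    expand.grid(glyph_id = c(tids, dids), size = spec$test_size,
                ecc = sides * spec$test_ecc, stringsAsFactors = FALSE))
  ensure_features(model, pairs, plc, calib, cache)
  same_sims <- numeric(0); diff_sims <- numeric(0)
  for (side in sides) {
    for (id in tids) {
      tf <- placement_features(model, pairs, id, spec$target_size,
                               side * spec$target_ecc, calib, cache)
      sf <- placement_features(model, pairs, id, spec$test_size,
                               side * spec$test_ecc, calib, cache)
      df <- placement_features(model, pairs, distractor_of(pairs, id),
                               spec$test_size, side * spec$test_ecc, calib,
                               cache)
      same_sims <- c(same_sims, condition_similarity(spec$metric, tf, sf))
      diff_sims <- c(diff_sims, condition_similarity(spec$metric, tf, df))
    }
  }
  ot <- optimal_threshold(same_sims, diff_sims)
  structure(list(accuracy = ot$accuracy, threshold = ot$threshold,
                 d_prime = dprime(ot$hit_rate, ot$fa_rate,
                                  n_same = length(same_sims),
                                  n_diff = length(diff_sims)),
                 hit_rate = ot$hit_rate, fa_rate = ot$fa_rate,
                 similarities_same = same_sims,
                 similarities_diff = diff_sims,
                 n_trials = length(same_sims) + length(diff_sims),
                 spec = spec),
            class = "condition_result")
}

#' @export
print.condition_result <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<condition_result> %s/%s: (%g', %g deg) -> (%g', %g deg): acc %.3f, d' %.2f (n=%d)\n",
    s$regime, s$metric, s$target_size, s$target_ecc, s$test_size, s$test_ecc,
    x$accuracy, x$d_prime, x$n_trials))
  invisible(x)
}

#' Raw same-glyph feature correlation versus eccentricity
#'
#' Mean similarity (under the chosen metric) between features of the same
#' glyph presented at fixation and at each listed eccentricity, averaged over
#' target glyphs and left/right presentation. This is the raw-correlation
#' check that representations of the same stimulus genuinely drift apart with
#' eccentricity, independent of any threshold.
#'
#' @param pairs A paired `glyph_set`.
#' @param size Letter size in arcmin.
#' @param eccs Eccentricities in degrees (0 allowed: gives 1 by identity).
#' @param model A model.
#' @param metric `"symmetric"` or `"asymmetric"`.
#' @param calib Full-field calibration.
#' @return Data frame with `eccentricity` and `mean_correlation`.
#' @export
correlation_vs_eccentricity <- function(pairs, size, eccs, model,
                                        metric = c("symmetric", "asymmetric"),
                                        calib = model$config$calibration) {
  metric <- match.arg(metric)
  tids <- target_ids(pairs)
  cache <- new.env(parent = emptyenv())
  plc <- expand.grid(glyph_id = tids, size = size,
                     ecc = unique(c(0, eccs, -eccs)),
                     stringsAsFactors = FALSE)
  ensure_features(model, pairs, plc, calib, cache)
  out <- vapply(eccs, function(D) {
    sides <- if (D != 0) c(1, -1) else 1
    mean(vapply(tids, function(id) {
      f0 <- placement_features(model, pairs, id, size, 0, calib, cache)
      mean(vapply(sides, function(side) {
        fD <- placement_features(model, pairs, id, size, side * D, calib,
                                 cache)
        condition_similarity(metric, f0, fD)
      }, numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  data.frame(eccentricity = eccs, mean_correlation = out)
}
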