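# Similarity metrics, threshold optimisation, and d-prime.

undefined_correlation_error <- function(msg) {
  stop(structure(class = c("foveanet_undefined_correlation", "error",
                           "condition"),
                 list(message = msg, call = NULL)))
}

#' Pearson correlation between two feature vectors
#'
#' Standard Pearson r. A constant vector makes the correlation undefined; by
#' package convention the similarity is then taken to be 0 (with a warning),
#' which only arises for blank or fully rectified-away inputs.
#'
#' @param a,b Equal-length numeric vectors (length >= 2).
#' @param on_constant `"zero"` (default) or `"error"`.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_cor <- function(a, b, on_constant = c("zero", "error")) {
  on_constant <- match.arg(on_constant)
  if (length(a) != length(b) || length(a) < 2L) {
    stop("feature vectors must have equal length >= 2", call. = FALSE)
  }
  ca <- a - mean(a); cb <- b - mean(b)
  va <- sum(ca * ca); vb <- sum(cb * cb)
  if (va <= 0 || vb <= 0) {
    if (on_constant == "error") {
      undefined_correlation_error("correlation undefined for constant vector")
    }
    warning("constant feature vector: similarity taken as 0", call. = FALSE)
    return(0)
  }
  sum(ca * cb) / sqrt(va * vb)
}

#' Symmetric (scale-pooled) similarity
#'
#' Pearson correlation between the scale-pooled feature vectors of target and
#' test; symmetric under argument swap. This is the metric of the original
#' pooled-template model and of the single-scale control (whose features are
#' one vector per image, so no asymmetry is possible).
#'
#' @param target,test Feature lists from [model_features()] internals or
#'   plain numeric vectors (pooled features).
#' @return Correlation.
#' @export
symmetric_similarity <- function(target, test) {
  tv <- if (is.list(target)) target$pooled else target
  sv <- if (is.list(test)) test$pooled else test
  pearson_cor(tv, sv)
}

#' Asymmetric (channel-selection) similarity
#'
#' The stored target keeps its per-channel templates (the feature bank); the
#' test presentation is scale-pooled. The similarity is the maximum over
#' channels of the Pearson correlation between a stored channel template and
#' the pooled test feature -- the channel of the stored letter most
#' correlated with the test is selected, and the threshold is applied to that
#' correlation. Because only the target retains multiple resolutions, the
#' metric is not symmetric in presentation order: a foveally learned target
#' offers templates at the full range of resolutions, a peripherally learned
#' one only low-pass versions. With a single-channel bank this reduces to
#' [symmetric_similarity()].
#'
#' The stored template set consists of the per-channel feature vectors plus,
#' by default, their element-wise maximum (the scale-pooled vector): the
#' pooled representation is what the model itself computes at learning time,
#' so it is available in memory along with the channel templates. Including
#' it makes the baseline condition (identical target and test presentation)
#' score exactly 1 while leaving the learning-order asymmetry intact; set
#' `include_pooled = FALSE` for the bank-only variant.
#'
#' @param target_bank Matrix `feature_len` x `n_channels` (or a feature list
#'   with a `bank` element).
#' @param test_pooled Pooled feature vector of the test (or a feature list).
#' @param include_pooled Also offer the stored scale-pooled vector as a
#'   template (default `TRUE`).
#' @return List with `similarity` (max correlation) and `channel` (argmax;
#'   1-based bank channel, or 0 when the pooled template wins).
#' @export
asymmetric_similarity <- function(target_bank, test_pooled,
                                  include_pooled = TRUE) {
  bank <- if (is.list(target_bank)) target_bank$bank else target_bank
  tv <- if (is.list(test_pooled)) test_pooled$pooled else test_pooled
  if (include_pooled && ncol(bank) > 1L) {
    pooled_t <- if (is.list(target_bank) && !is.null(target_bank$pooled)) {
      target_bank$pooled
    } else {
      do.call(pmax, lapply(seq_len(ncol(bank)), function(k) bank[, k]))
    }
    bank <- cbind(pooled_t, bank)
    offset <- 1L
  } else {
    offset <- 0L
  }
  nch <- ncol(bank)
  cors <- numeric(nch)
  n_const <- 0L
  for (k in seq_len(nch)) {
    ck <- bank[, k] - mean(bank[, k])
    vk <- sum(ck * ck)
    if (vk <= 0) { n_const <- n_const + 1L; cors[k] <- -Inf; next }
    cors[k] <- pearson_cor(bank[, k], tv)
  }
  if (n_const == nch) {
    undefined_correlation_error("all stored channels are constant")
  }
  if (n_const > 0L) {
    warning("constant stored channel(s) skipped in channel selection",
            call. = FALSE)
  }
  k <- which.max(cors)
  list(similarity = cors[k], channel = k - offset)
}

#' Accuracy-maximising similarity threshold
#'
#' A trial is called "same" iff its similarity exceeds the threshold t;
#' accuracy(t) = (#\{same > t\} + #\{diff <= t\}) / (n_same + n_diff).
#' Candidate thresholds are the midpoints between adjacent sorted
#' similarities plus sentinels below and above all values, which exactly
#' covers every achievable classification; the first maximiser (smallest
#' threshold) is returned, so results are reproducible. This per-condition
#' maximisation mirrors the model-evaluation protocol; note it is an
#' optimistic bound on generalisation accuracy.
#'
#' @param same_sims Similarities of same-identity trials (non-empty).
#' @param diff_sims Similarities of different-identity trials (non-empty).
#' @return List with `threshold`, `accuracy`, `hit_rate`, `fa_rate`.
#' @export
optimal_threshold <- function(same_sims, diff_sims) {
  if (length(same_sims) == 0L || length(diff_sims) == 0L) {
    stop("both similarity lists must be non-empty", call. = FALSE)
  }
  all_s <- sort(unique(c(same_sims, diff_sims)))
  cand <- c(all_s[1L] - 1,
            if (length(all_s) > 1L) (all_s[-1L] + all_s[-length(all_s)]) / 2,
            all_s[length(all_s)] + 1)
  n <- length(same_sims) + length(diff_sims)
  acc <- vapply(cand, function(t) {
    (sum(same_sims > t) + sum(diff_sims <= t)) / n
  }, numeric(1))
  k <- which.max(acc)
  t <- cand[k]
  list(threshold = t, accuracy = acc[k],
       hit_rate = mean(same_sims > t), fa_rate = mean(diff_sims > t))
}

#' Signal-detection sensitivity d-prime
#'
#' `qnorm(hit_rate) - qnorm(fa_rate)`. Rates of exactly 0 or 1 are corrected
#' with the log-linear rule (0.5 added to the corresponding count, 1 to the
#' trial count) using the supplied trial counts, so non-degenerate rates are
#' passed through unchanged.
#'
#' @param hit_rate,fa_rate Rates in \[0, 1\].
#' @param n_same,n_diff Trial counts behind the rates; required only when a
#'   rate is exactly 0 or 1.
#' @return d-prime.
#' @export
dprime <- function(hit_rate, fa_rate, n_same = NULL, n_diff = NULL) {
  fix <- function(r, n) {
    if (r > 0 && r < 1) return(r)
    if (is.null(n)) {
      stop("trial count needed to correct a rate of 0 or 1", call. = FALSE)
    }
    (r * n + 0.5) / (n + 1)
  }
  stats::qnorm(fix(hit_rate, n_same)) - stats::qnorm(fix(fa_rate, n_diff))
}

#' Re-score similarities at a fixed (global) threshold
#'
#' Per-condition optimal thresholds are an optimistic in-sample bound; for
#' robustness analyses a single threshold can be fixed across conditions and
#' each condition re-scored with it. Accuracy, hit/false-alarm rates, and
#' d-prime are recomputed from the stored similarity lists under the same
#' decision rule ("same" iff similarity > threshold).
#'
#' @param result A `condition_result` from [run_condition()].
#' @param threshold Fixed similarity threshold in \[-1, 1\].
#' @return A `condition_result` with the fixed threshold and re-derived
#'   accuracy, rates, and d-prime.
#' @export
rescore_at_threshold <- function(result, threshold) {
  stopifnot(inherits(result, "condition_result"))
  same <- result$similarities_same
  diff <- result$similarities_diff
  n <- length(same) + length(diff)
  result$threshold <- threshold
  result$accuracy <- (sum(same > threshold) + sum(diff <= threshold)) / n
  result$hit_rate <- mean(same > threshold)
  result$fa_rate <- mean(diff > threshold)
  result$d_prime <- dprime(result$hit_rate, result$fa_rate,
                           n_same = length(same), n_diff = length(diff))
  result
}
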