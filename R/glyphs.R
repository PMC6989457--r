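# Procedural glyph generation.
#
# Glyphs are stroke skeletons (thick line segments between jittered lattice
# points on the unit square) rasterised with one pixel of anti-aliasing.
# Novel target/distractor pairs share their skeleton except for one stroke,
# emulating letter pairs that differ in a single structural element; training
# classes are fixed skeletons with per-item endpoint/thickness jitter,
# emulating a small handwritten-character dataset.

# distance from pixel centres to a segment
.seg_dist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- dx * dx + dy * dy
  if (L2 < 1e-12) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- ((px - x1) * dx + (py - y1) * dy) / L2
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

# rasterise a stroke table (cols x1,y1,x2,y2,w in unit coords) to px x px ink
draw_strokes <- function(strokes, px = 64L) {
  cc <- (seq_len(px) - 0.5) / px
  gx <- rep(cc, each = px)   # column-major: x varies over columns
  gy <- rep(cc, times = px)
  aa <- 1 / px               # one-pixel anti-alias ramp
  ink <- numeric(px * px)
  for (i in seq_len(nrow(strokes))) {
    s <- strokes[i, ]
    d <- .seg_dist(gx, gy, s[[1]], s[[2]], s[[3]], s[[4]])
    cov <- pmin(1, pmax(0, (s[[5]] / 2 - d) / aa + 0.5))
    ink <- pmax(ink, cov)
  }
  matrix(ink, px, px)
}

.lattice <- function() as.matrix(expand.grid(x = seq(0.18, 0.82, length.out = 4),
                                             y = seq(0.18, 0.82, length.out = 4)))

# crop the ink bounding box, pad to square (preserving aspect), resample back
# to ref_px: the nominal letter size then equals the rendered ink extent
normalize_glyph <- function(ink, ref_px, tol = 0.05) {
  hit <- ink > tol
  if (!any(hit)) return(ink)
  rr <- range(which(apply(hit, 1L, any)))
  cr <- range(which(apply(hit, 2L, any)))
  crop <- ink[rr[1L]:rr[2L], cr[1L]:cr[2L], drop = FALSE]
  side <- max(nrow(crop), ncol(crop))
  sq <- matrix(0, side, side)
  r0 <- (side - nrow(crop)) %/% 2L; c0 <- (side - ncol(crop)) %/% 2L
  sq[r0 + seq_len(nrow(crop)), c0 + seq_len(ncol(crop))] <- crop
  resample_image(sq, ref_px)
}

# one random stroke between two distinct lattice points
.rand_stroke <- function(lat, w_range = c(0.08, 0.13)) {
  repeat {
    ij <- sample(nrow(lat), 2L)
    p <- lat[ij[1L], ]; q <- lat[ij[2L], ]
    if (sum((p - q)^2) > 0.05) break
  }
  c(p[1L], p[2L], q[1L], q[2L], stats::runif(1, w_range[1L], w_range[2L]))
}

.rand_skeleton <- function(n_strokes, lat = .lattice()) {
  t(vapply(seq_len(n_strokes), function(i) .rand_stroke(lat), numeric(5)))
}

#' Generate novel target/distractor glyph pairs
#'
#' Procedurally generates `n_pairs` target glyphs, each paired with a
#' structurally similar distractor that shares the stroke skeleton except for
#' one re-drawn stroke. These play the role of unfamiliar letter pairs in the
#' one-shot same/different protocol and are disjoint by construction from the
#' procedural training classes (which use their own seeded skeletons).
#'
#' @param n_pairs Number of pairs (>= 1). The reference stimulus set has 27.
#' @param seed Integer seed; the set is bit-reproducible given the seed.
#' @param ref_px Reference raster resolution per glyph.
#' @return A `glyph_set`: named list of ink rasters in \[0,1\] (targets
#'   `g01..`, distractors `g01d..`), a `pairing` map target -> distractor,
#'   `labels = NULL`.
#' @export
make_novel_pairs <- function(n_pairs, seed = 0L, ref_px = 64L) {
  stopifnot(n_pairs >= 1)
  with_seed(seed, {
    lat <- .lattice()
    glyphs <- list()
    pairing <- character(0)
    for (i in seq_len(n_pairs)) {
      n_str <- sample(3:4, 1L)
      sk <- .rand_skeleton(n_str, lat)
      tg <- normalize_glyph(draw_strokes(sk, ref_px), ref_px)
      repeat {
        sk2 <- sk
        j <- sample(n_str, 1L)
        sk2[j, ] <- .rand_stroke(lat)
        di <- normalize_glyph(draw_strokes(sk2, ref_px), ref_px)
        if (mean(abs(di - tg)) > 0.01) break
      }
      tid <- sprintf("g%02d", i); did <- sprintf("g%02dd", i)
      glyphs[[tid]] <- tg
      glyphs[[did]] <- di
      pairing[tid] <- did
    }
    new_glyph_set(glyphs, pairing = pairing, ref_px = ref_px, seed = seed)
  })
}

#' Generate labelled training glyph classes
#'
#' Emulates a small handwritten-character dataset: each class is a fixed
#' stroke skeleton; items are drawn by jittering stroke endpoints and widths,
#' standing in for handwriting variability. Used to build the supervised
#' training set for the networks.
#'
#' @param n_classes Number of classes (default 10, digit-like).
#' @param n_items Items per class.
#' @param seed Integer seed.
#' @param ref_px Raster resolution.
#' @param jitter_sd Endpoint jitter standard deviation in unit-square coords.
#' @return A labelled `glyph_set` (ids `cCC_iII`, `labels` = class index).
#' @export
make_glyph_classes <- function(n_classes = 10L, n_items = 20L, seed = 0L,
                               ref_px = 64L, jitter_sd = 0.025) {
  stopifnot(n_classes >= 1, n_items >= 1)
  with_seed(seed, {
    lat <- .lattice()
    glyphs <- list(); labels <- integer(0)
    for (cl in seq_len(n_classes)) {
      n_str <- sample(2:4, 1L)
      sk <- .rand_skeleton(n_str, lat)
      for (it in seq_len(n_items)) {
        sk2 <- sk
        sk2[, 1:4] <- pmin(0.95, pmax(0.05, sk2[, 1:4] +
                                        stats::rnorm(4L * n_str, sd = jitter_sd)))
        sk2[, 5] <- sk2[, 5] * stats::runif(n_str, 0.85, 1.15)
        id <- sprintf("c%02d_i%03d", cl, it)
        glyphs[[id]] <- normalize_glyph(draw_strokes(sk2, ref_px), ref_px)
        labels[id] <- cl
      }
    }
    new_glyph_set(glyphs, pairing = NULL, labels = labels,
                  ref_px = ref_px, seed = seed)
  })
}

new_glyph_set <- function(glyphs, pairing = NULL, labels = NULL,
                          ref_px = 64L, seed = NA_integer_) {
  if (!is.null(pairing)) {
    if (any(pairing == names(pairing))) {
      stop("a distractor must differ from its target", call. = FALSE)
    }
  }
  structure(list(glyphs = glyphs, pairing = pairing, labels = labels,
                 ref_px = ref_px, seed = seed),
            class = "glyph_set")
}

#' @export
print.glyph_set <- function(x, ...) {
  cat(sprintf("<glyph_set> %d glyphs (%d px), %s%s\n",
              length(x$glyphs), x$ref_px,
              if (is.null(x$pairing)) "unpaired"
              else sprintf("%d target/distractor pairs", length(x$pairing)),
              if (is.null(x$labels)) ""
              else sprintf(", %d classes", length(unique(x$labels)))))
  invisible(x)
}

#' @export
length.glyph_set <- function(x) length(x$glyphs)

glyph_raster <- function(glyphs, id) {
  g <- glyphs$glyphs[[id]]
  if (is.null(g)) stop(sprintf("unknown glyph id '%s'", id), call. = FALSE)
  g
}

#' Target ids of a paired glyph set
#' @param glyphs A `glyph_set` with a pairing.
#' @return Character vector of target ids.
#' @export
target_ids <- function(glyphs) {
  if (is.null(glyphs$pairing)) stop("glyph set has no pairing", call. = FALSE)
  names(glyphs$pairing)
}

#' Distractor id paired with a target
#' @param glyphs A `glyph_set` with a pairing.
#' @param id A target glyph id.
#' @return The paired distractor id.
#' @export
distractor_of <- function(glyphs, id) {
  d <- glyphs$pairing[id]
  if (is.null(glyphs$pairing) || is.na(d)) {
    stop(sprintf("no distractor paired with '%s'", id), call. = FALSE)
  }
  unname(d)
}
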