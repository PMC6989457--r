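#' Stimulus specification
#'
#' Describes one glyph placement on the simulated visual field: identity,
#' angular size in arcmin, signed horizontal eccentricity in degrees
#' (negative = left visual field, 0 = fixation), and contrast polarity.
#'
#' @param glyph_id Glyph identifier present in the glyph set used at render time.
#' @param size Letter size in arcmin (> 0).
#' @param eccentricity Signed horizontal eccentricity in degrees.
#' @param polarity `"dark-on-light"` (default, black letter on white field) or
#'   `"light-on-dark"`.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(glyph_id, size, eccentricity = 0,
                          polarity = c("dark-on-light", "light-on-dark")) {
  polarity <- match.arg(polarity)
  if (!is.numeric(size) || size <= 0) {
    stop("size must be a positive number of arcmin", call. = FALSE)
  }
  structure(list(glyph_id = glyph_id, size = size,
                 eccentricity = eccentricity, polarity = polarity),
            class = "stimulus_spec")
}

out_of_field_error <- function(msg) {
  stop(structure(class = c("foveanet_out_of_field", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# check the stimulus fits inside the field (size/120 = arcmin radius in deg)
check_in_field <- function(spec, calib) {
  if (abs(spec$eccentricity) + spec$size / 120 > calib$field_span / 2 + 1e-9) {
    out_of_field_error(sprintf(
      "stimulus at %.2f deg of size %.1f arcmin exceeds the %.2f deg field",
      spec$eccentricity, spec$size, calib$field_span))
  }
  invisible(TRUE)
}

# --- visual_field -----------------------------------------------------------

# Either dense (pixels) or sparse (patch + offset within an implicit uniform
# background). Sparse fields keep training sets small in memory; all samplers
# go through field_boxgrid()/field_matrix() and treat the two identically.
new_visual_field <- function(n, calibration, background, pixels = NULL,
                             patch = NULL, offset = NULL, spec = NULL) {
  structure(list(n = as.integer(n), calibration = calibration,
                 background = background, pixels = pixels,
                 patch = patch, offset = offset, spec = spec,
                 cache = new.env(parent = emptyenv())),
            class = "visual_field")
}

#' @export
print.visual_field <- function(x, ...) {
  cat(sprintf("<visual_field> %d x %d px (%s), background %.2f%s\n",
              x$n, x$n, if (is.null(x$pixels)) "sparse" else "dense",
              x$background,
              if (is.null(x$spec)) ""
              else sprintf(", glyph '%s' %g arcmin at %g deg",
                           x$spec$glyph_id, x$spec$size, x$spec$eccentricity)))
  invisible(x)
}

#' Materialise a visual field as a pixel matrix
#' @param x A `visual_field`.
#' @param ... Unused.
#' @return Numeric matrix of side `x$n`, values in \[0, 1\].
#' @export
as.matrix.visual_field <- function(x, ...) field_matrix(x)

field_matrix <- function(vf) {
  if (!is.null(vf$pixels)) return(vf$pixels)
  M <- matrix(vf$background, vf$n, vf$n)
  if (!is.null(vf$patch)) {
    r0 <- vf$offset[1L] + 1L; c0 <- vf$offset[2L] + 1L
    M[r0:(r0 + nrow(vf$patch) - 1L), c0:(c0 + ncol(vf$patch) - 1L)] <- vf$patch
  }
  M
}

# integral image of (values - background); zero outside the stored support
field_integral <- function(vf) {
  if (is.null(vf$cache$I)) {
    Z <- if (!is.null(vf$pixels)) vf$pixels - vf$background
         else if (!is.null(vf$patch)) vf$patch - vf$background
         else matrix(0, 1L, 1L)
    vf$cache$I <- integral_image(Z)
  }
  vf$cache$I
}

# box means over a uniform grid given in continuous field coordinates
# (origin = field top-left corner); works for dense and sparse fields and for
# boxes extending beyond the field (background fills in). Only grid cells
# whose boxes intersect the stored support are interpolated; everything else
# is background by construction.
field_boxgrid <- function(vf, ey, ex) {
  if (!is.null(vf$pixels)) {
    off <- c(0, 0); hs <- dim(vf$pixels)
  } else if (!is.null(vf$patch)) {
    off <- vf$offset; hs <- dim(vf$patch)
  } else {
    return(matrix(vf$background, length(ey) - 1L, length(ex) - 1L))
  }
  ny <- length(ey) - 1L; nx <- length(ex) - 1L
  yr <- which(ey[-1L] > off[1L] & ey[-(ny + 1L)] < off[1L] + hs[1L])
  xr <- which(ex[-1L] > off[2L] & ex[-(nx + 1L)] < off[2L] + hs[2L])
  out <- matrix(vf$background, ny, nx)
  if (length(yr) == 0L || length(xr) == 0L) return(out)
  yi <- c(yr, yr[length(yr)] + 1L); xi <- c(xr, xr[length(xr)] + 1L)
  out[yr, xr] <- box_grid_mean(field_integral(vf),
                               ey[yi] - off[1L], ex[xi] - off[2L],
                               bg = vf$background)
  out
}

# --- rendering --------------------------------------------------------------

#' Render a glyph on the simulated visual field
#'
#' The glyph raster is resampled to `arcmin_to_pixels(spec$size)` pixels
#' (area-averaged when shrinking, bilinear when enlarging) and its centre is
#' placed at a horizontal offset of `round(eccentricity * pixels_per_degree)`
#' pixels from the field centre; the rest of the field is the uniform
#' background. Placement is rounded to whole pixels, so two renderings that
#' differ only by an integral pixel shift are exact translations of each
#' other. Rendering is deterministic.
#'
#' @param spec A [stimulus_spec()].
#' @param glyphs A `glyph_set` containing `spec$glyph_id`.
#' @param calib A [field_calibration()]; the output raster side is
#'   `calib$field_pixels`. A compact calibration (smaller `field_span`) may be
#'   used: samplers treat everything beyond the raster as background.
#' @param sparse If `TRUE`, return a memory-compact field that stores only the
#'   glyph patch; `as.matrix()` materialises it.
#' @return A `visual_field`.
#' @export
render_stimulus <- function(spec, glyphs, calib = field_calibration(),
                            sparse = FALSE) {
  check_in_field(spec, calib)
  ink <- glyph_raster(glyphs, spec$glyph_id)
  t_px <- arcmin_to_pixels(spec$size, calib)
  ink <- resample_image(ink, t_px)
  N <- calib$field_pixels
  off <- as.integer(round(deg_to_px(spec$eccentricity, calib)))
  r0 <- as.integer(round((N - t_px) / 2)) + 1L
  c0 <- r0 + off
  if (r0 < 1L || c0 < 1L || r0 + t_px - 1L > N || c0 + t_px - 1L > N) {
    out_of_field_error("stimulus exceeds the field raster")
  }
  dark <- spec$polarity == "dark-on-light"
  bg <- if (dark) 1 else 0
  patch <- if (dark) 1 - ink else ink
  if (sparse) {
    new_visual_field(N, calib, bg, patch = patch,
                     offset = c(r0 - 1L, c0 - 1L), spec = spec)
  } else {
    M <- matrix(bg, N, N)
    M[r0:(r0 + t_px - 1L), c0:(c0 + t_px - 1L)] <- patch
    new_visual_field(N, calib, bg, pixels = M, spec = spec)
  }
}

#' Blank visual field
#' @param calib A [field_calibration()].
#' @param background Background value in \[0, 1\].
#' @return A `visual_field` with uniform background.
#' @export
blank_field <- function(calib = field_calibration(), background = 1) {
  new_visual_field(calib$field_pixels, calib, background,
                   pixels = matrix(background, calib$field_pixels,
                                   calib$field_pixels))
}

#' Convert a rendered field to network polarity
#'
#' Stimuli are rendered dark-on-light as displayed to observers, then
#' intensity-inverted before entering a network so that the stimulus is
#' positive on a zero background (zero padding of convolutions then matches
#' the background).
#'
#' @param vf A `visual_field`.
#' @return A `visual_field` with background 0 and stimulus-positive values.
#' @export
network_input <- function(vf) {
  if (vf$background == 0) return(vf)
  new_visual_field(vf$n, vf$calibration, 0,
                   pixels = if (is.null(vf$pixels)) NULL else 1 - vf$pixels,
                   patch = if (is.null(vf$patch)) NULL else 1 - vf$patch,
                   offset = vf$offset, spec = vf$spec)
}

# bounding box of non-background pixels (rows, cols); NULL if blank
stimulus_bbox <- function(vf, tol = 1e-3) {
  M <- field_matrix(vf)
  hit <- abs(M - vf$background) > tol
  if (!any(hit)) return(NULL)
  rows <- range(which(apply(hit, 1L, any)))
  cols <- range(which(apply(hit, 2L, any)))
  list(rows = rows, cols = cols,
       height = diff(rows) + 1L, width = diff(cols) + 1L)
}

# --- training sets ----------------------------------------------------------

#' Augmentation policy for training-set generation
#'
#' @param size_range Interval of letter sizes in arcmin.
#' @param ecc_range Interval of eccentricities in degrees.
#' @param samples_per_item Augmented renderings per base glyph (>= 1).
#' @param seed Integer seed.
#' @return An `augmentation_policy`.
#' @export
augmentation_policy <- function(size_range = c(20, 120), ecc_range = c(-2, 2),
                                samples_per_item = 4L, seed = 0L) {
  stopifnot(length(size_range) == 2, length(ecc_range) == 2,
            size_range[1] > 0, diff(size_range) >= 0, diff(ecc_range) >= 0,
            samples_per_item >= 1)
  structure(list(size_range = size_range, ecc_range = ecc_range,
                 samples_per_item = as.integer(samples_per_item),
                 seed = as.integer(seed)),
            class = "augmentation_policy")
}

#' Build a labelled training set of rendered stimuli
#'
#' For each labelled glyph, draws `samples_per_item` (size, eccentricity)
#' placements uniformly from the policy ranges and renders them, preserving
#' the class label. This is the scale/shift augmentation used to train both
#' networks. Deterministic in the policy seed.
#'
#' @param glyphs A labelled `glyph_set` (see [make_glyph_classes()]).
#' @param policy An [augmentation_policy()].
#' @param calib A [field_calibration()].
#' @param sparse Render memory-compact fields (default `TRUE`).
#' @return List with `images` (list of `visual_field`), `labels` (integer
#'   class per image), and `specs` (data frame of placements).
#' @export
build_training_set <- function(glyphs, policy, calib = field_calibration(),
                               sparse = TRUE) {
  if (is.null(glyphs$labels)) {
    stop("training glyphs must carry class labels", call. = FALSE)
  }
  worst <- stimulus_spec("x", size = policy$size_range[2L],
                         eccentricity = max(abs(policy$ecc_range)))
  check_in_field(worst, calib)
  with_seed(policy$seed, {
    ids <- names(glyphs$glyphs)
    n <- length(ids) * policy$samples_per_item
    images <- vector("list", n)
    labels <- integer(n)
    specs <- data.frame(glyph_id = character(n), size = numeric(n),
                        eccentricity = numeric(n), label = integer(n))
    k <- 0L
    for (id in ids) {
      for (s in seq_len(policy$samples_per_item)) {
        k <- k + 1L
        sz <- stats::runif(1, policy$size_range[1L], policy$size_range[2L])
        ec <- stats::runif(1, policy$ecc_range[1L], policy$ecc_range[2L])
        sp <- stimulus_spec(id, sz, ec)
        images[[k]] <- render_stimulus(sp, glyphs, calib, sparse = sparse)
        labels[k] <- glyphs$labels[[id]]
        specs[k, ] <- list(id, sz, ec, labels[k])
      }
    }
    list(images = images, labels = labels, specs = specs, seed = policy$seed)
  })
}
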