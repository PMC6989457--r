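# Plain-text serialisation: PGM images, JSON manifests/configs, CSV reports,
# and an optional reader for the IDX format used by handwritten-digit dumps.

#' Write a grayscale image as plain-text PGM (P2)
#'
#' @param M Numeric matrix with values in \[0, 1\], or a `visual_field`.
#' @param path Output path.
#' @param maxval Grey levels (default 255).
#' @return The path, invisibly.
#' @export
write_pgm <- function(M, path, maxval = 255L) {
  if (inherits(M, "visual_field")) M <- as.matrix(M)
  v <- round(pmin(pmax(M, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(M), nrow(M)), as.character(maxval)), con)
  write(t(v), file = con, ncolumns = ncol(M))
  invisible(path)
}

#' Read a plain-text PGM (P2) image
#' @param path File path.
#' @return Matrix with values in \[0, 1\].
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1L] != "P2") stop("only plain (P2) PGM is supported", call. = FALSE)
  w <- as.integer(toks[2L]); h <- as.integer(toks[3L])
  maxval <- as.numeric(toks[4L])
  vals <- as.numeric(toks[-(1:4)])
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxval
}

#' Write a glyph-set manifest as JSON
#'
#' Records glyph ids, pairings, labels, reference resolution and seed so a
#' generated set can be reproduced exactly.
#'
#' @param glyphs A `glyph_set`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_glyph_manifest <- function(glyphs, path) {
  jsonlite::write_json(
    list(ids = names(glyphs$glyphs),
         pairing = as.list(glyphs$pairing),
         labels = as.list(glyphs$labels),
         ref_px = glyphs$ref_px, seed = glyphs$seed),
    path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

# CSV + JSON sidecar with config hash and seed
write_report <- function(report, stem, config, seed) {
  utils::write.csv(report, paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(config_hash = config_hash(config), seed = seed,
                            profile = config$profile),
                       paste0(stem, "_meta.json"), auto_unbox = TRUE)
  invisible(stem)
}

#' Read an IDX-format raster file (optional handwritten-digit adapter)
#'
#' Reads the big-endian IDX format in which the classic handwritten-digit
#' dataset is distributed. The dataset itself is not bundled; this adapter
#' exists so locally downloaded dumps can be substituted for the procedural
#' training classes.
#'
#' @param path Path to an (uncompressed) IDX file.
#' @param n_max Maximum number of items to read.
#' @return For image files, a list of matrices scaled to \[0, 1\]; for label
#'   files, an integer vector.
#' @export
read_idx <- function(path, n_max = Inf) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  ndim <- magic %% 256L
  dims <- readBin(con, "integer", ndim, size = 4L, endian = "big")
  n <- min(dims[1L], n_max)
  if (ndim == 1L) {
    as.integer(readBin(con, "integer", n, size = 1L, signed = FALSE))
  } else {
    h <- dims[2L]; w <- dims[3L]
    lapply(seq_len(n), function(i) {
      v <- readBin(con, "integer", h * w, size = 1L, signed = FALSE)
      matrix(v, h, w, byrow = TRUE) / 255
    })
  }
}

#' Wrap externally loaded rasters as a labelled glyph set
#'
#' @param images List of grayscale matrices, ink-positive in \[0, 1\].
#' @param labels Integer labels (1-based classes).
#' @param ref_px Common resolution; images are resampled to it.
#' @return A labelled `glyph_set` usable with [build_training_set()].
#' @export
glyph_set_from_rasters <- function(images, labels, ref_px = 64L) {
  stopifnot(length(images) == length(labels))
  glyphs <- list()
  lab <- integer(0)
  for (i in seq_along(images)) {
    id <- sprintf("x%05d", i)
    glyphs[[id]] <- resample_image(images[[i]], ref_px)
    lab[id] <- as.integer(labels[i])
  }
  new_glyph_set(glyphs, labels = lab, ref_px = ref_px)
}

#' Serialise a crop pyramid as a PGM stack plus JSON metadata
#'
#' Writes one plain-text PGM per scale channel (`<stem>_chNN.pgm`) and a
#' JSON sidecar (`<stem>.json`) with spans, grid, and calibration, so a
#' pyramid can be inspected or reloaded without the package.
#'
#' @param pyramid A `crop_pyramid`.
#' @param stem Output path stem.
#' @return The stem, invisibly.
#' @export
write_pyramid <- function(pyramid, stem) {
  n <- dim(pyramid$channels)[3L]
  rng <- range(pyramid$channels)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  for (k in seq_len(n)) {
    write_pgm((pyramid$channels[, , k] - rng[1L]) / scale,
              sprintf("%s_ch%02d.pgm", stem, k))
  }
  jsonlite::write_json(
    list(n_channels = n, grid = pyramid$grid, spans_px = pyramid$spans_px,
         spans_deg = pyramid$spans_deg, value_range = rng,
         background = pyramid$background,
         pixels_per_degree = pyramid$calibration$pixels_per_degree),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Read back a serialised crop pyramid
#' @param stem Path stem used by [write_pyramid()].
#' @return A `crop_pyramid` (values quantised to the PGM grey levels).
#' @export
read_pyramid <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  ch <- array(0, c(meta$grid, meta$grid, meta$n_channels))
  for (k in seq_len(meta$n_channels)) {
    ch[, , k] <- read_pgm(sprintf("%s_ch%02d.pgm", stem, k)) *
      diff(meta$value_range) + meta$value_range[1L]
  }
  structure(list(channels = ch, spans_px = meta$spans_px,
                 spans_deg = meta$spans_deg, grid = meta$grid,
                 calibration = field_calibration(meta$pixels_per_degree),
                 background = meta$background),
            class = "crop_pyramid")
}
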