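#' Visual-field calibration
#'
#' A `field_calibration` fixes the conversion between pixels and visual angle
#' for the simulated visual field. The default is 450 pixels per degree, the
#' value used throughout the model experiments, with a field of view of
#' approximately 19.2 degrees (the span of the coarsest crop of the default
#' ten-channel pyramid, 225 * 1.5^9 pixels).
#'
#' @param pixels_per_degree Pixels per degree of visual angle (px/deg).
#' @param field_span Field of view in degrees. Defaults to 8650/450, i.e.
#'   about 19.22 deg, independent of `pixels_per_degree`.
#' @param field_pixels Side of the square field raster in pixels. If given,
#'   `field_span` is derived from it; otherwise it is
#'   `round(pixels_per_degree * field_span)`.
#' @return An object of class `field_calibration` with fields
#'   `pixels_per_degree`, `field_span`, `field_pixels`.
#' @examples
#' calib <- field_calibration()
#' calib$field_pixels  # 8650
#' arcmin_to_pixels(30, calib)  # 225
#' @export
field_calibration <- function(pixels_per_degree = 450,
                              field_span = 8650 / 450,
                              field_pixels = NULL) {
  stopifnot(is.numeric(pixels_per_degree), pixels_per_degree > 0)
  if (is.null(field_pixels)) {
    field_pixels <- as.integer(round(pixels_per_degree * field_span))
  } else {
    field_pixels <- as.integer(field_pixels)
    field_span <- field_pixels / pixels_per_degree
  }
  if (field_pixels <= 0L) stop("field_pixels must be positive", call. = FALSE)
  structure(
    list(pixels_per_degree = pixels_per_degree,
         field_span = field_span,
         field_pixels = field_pixels),
    class = "field_calibration"
  )
}

#' @export
print.field_calibration <- function(x, ...) {
  cat(sprintf("<field_calibration> %g px/deg, %.3f deg span, %d px\n",
              x$pixels_per_degree, x$field_span, x$field_pixels))
  invisible(x)
}

#' Convert a stimulus size in arcmin to pixels
#'
#' One arcmin is 1/60 degree, so a 30-arcmin letter occupies
#' `round(30/60 * 450) = 225` pixels under the default calibration.
#'
#' @param size Size in arcmin; must be positive.
#' @param calib A [field_calibration()].
#' @return Integer number of pixels.
#' @export
arcmin_to_pixels <- function(size, calib = field_calibration()) {
  if (!is.numeric(size) || any(size <= 0)) {
    stop("size must be a positive number of arcmin", call. = FALSE)
  }
  as.integer(round(size / 60 * calib$pixels_per_degree))
}

# degrees -> continuous pixels (unrounded)
deg_to_px <- function(deg, calib) deg * calib$pixels_per_degree

# restore the caller's RNG state after running seeded code
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
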