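#' Multi-scale crop pyramid specification
#'
#' The network input is a set of centred square crops of the visual field
#' whose spans grow exponentially, each resampled (anti-aliased) to a common
#' grid. The fovea is thereby sampled at every resolution while the periphery
#' appears only in the coarse channels -- the model analogue of receptive
#' field sizes growing with eccentricity. Defaults: 10 crops growing by a
#' factor of 1.5 from a 225-px (0.5 deg) foveal crop, so the coarsest crop
#' spans 225 * 1.5^9 = 8650 px, about 19.2 deg at 450 px/deg.
#'
#' @param n_channels Number of scale channels.
#' @param growth_factor Geometric growth factor of the crop spans.
#' @param smallest_span Foveal crop span in pixels.
#' @param common_grid Post-resampling grid side in pixels (all channels share
#'   it so that shared-weight convolution is well defined).
#' @return A `pyramid_spec`.
#' @export
pyramid_spec <- function(n_channels = 10L, growth_factor = 1.5,
                         smallest_span = 225L, common_grid = 225L) {
  stopifnot(n_channels >= 1, growth_factor > 0, smallest_span >= 1,
            common_grid >= 1)
  spec <- structure(list(n_channels = as.integer(n_channels),
                         growth_factor = growth_factor,
                         smallest_span = as.integer(smallest_span),
                         common_grid = as.integer(common_grid)),
                    class = "pyramid_spec")
  if (growth_factor > 1 && any(diff(crop_spans(spec)) <= 0)) {
    stop("crop spans must be strictly increasing", call. = FALSE)
  }
  spec
}

#' @export
print.pyramid_spec <- function(x, ...) {
  sp <- crop_spans(x)
  cat(sprintf("<pyramid_spec> %d channels x %g, spans %d..%d px, grid %d px\n",
              x$n_channels, x$growth_factor, sp[1L], sp[x$n_channels],
              x$common_grid))
  invisible(x)
}

#' Crop spans of a pyramid in pixels
#'
#' `round(smallest_span * growth_factor^(k-1))` for channels k = 1..n.
#'
#' @param spec A [pyramid_spec()].
#' @return Integer vector of spans, strictly increasing for growth > 1.
#' @export
crop_spans <- function(spec) {
  as.integer(round(spec$smallest_span *
                     spec$growth_factor^(seq_len(spec$n_channels) - 1L)))
}

#' Effective resolution of a scale channel
#'
#' After resampling a crop of span `s` pixels (i.e. `s / ppd` degrees) to the
#' common grid, the channel resolution is `common_grid / (s / ppd)` px/deg.
#' Channel 1 at defaults keeps the native 450 px/deg; each further channel is
#' coarser by the growth factor. Channel 5's resolution defines the
#' single-scale control network's input (its mid-resolution).
#'
#' @param spec A [pyramid_spec()].
#' @param k Channel index, 1-based (1 = foveal, finest).
#' @param calib A [field_calibration()].
#' @return Resolution in px/deg.
#' @export
channel_resolution <- function(spec, k, calib = field_calibration()) {
  if (k < 1 || k > spec$n_channels) {
    stop(sprintf("channel index %s out of 1..%d", k, spec$n_channels),
         call. = FALSE)
  }
  spans <- crop_spans(spec)
  spec$common_grid / (spans[k] / calib$pixels_per_degree)
}

#' Sample the multi-scale crop pyramid of a visual field
#'
#' Channel k is the centred square crop of `crop_spans(spec)[k]` pixels,
#' box-average resampled (anti-aliased, exact fractional-pixel areas) to the
#' common grid. Crops larger than the stored raster are padded with the
#' field's background value, so a compact rendering is equivalent to the full
#' field.
#'
#' @param image A `visual_field` (typically after [network_input()]).
#' @param spec A [pyramid_spec()].
#' @return A `crop_pyramid`: array `channels` of dim
#'   `(common_grid, common_grid, n_channels)` plus span metadata.
#' @export
sample_pyramid <- function(image, spec = pyramid_spec()) {
  g <- spec$common_grid
  spans <- crop_spans(spec)
  ppd <- image$calibration$pixels_per_degree
  ctr <- image$n / 2
  ch <- array(0, c(g, g, spec$n_channels))
  for (k in seq_len(spec$n_channels)) {
    s <- spans[k]
    e <- ctr - s / 2 + s * (0:g) / g
    ch[, , k] <- field_boxgrid(image, e, e)
  }
  structure(list(channels = ch, spans_px = spans, spans_deg = spans / ppd,
                 grid = g, calibration = image$calibration,
                 background = image$background),
            class = "crop_pyramid")
}

#' @export
print.crop_pyramid <- function(x, ...) {
  cat(sprintf("<crop_pyramid> %d channels, grid %d px, spans %.2f..%.2f deg\n",
              dim(x$channels)[3L], x$grid, min(x$spans_deg), max(x$spans_deg)))
  invisible(x)
}

#' Extract one channel of a crop pyramid
#' @param pyramid A `crop_pyramid`.
#' @param k Channel index (1 = foveal).
#' @return Matrix of the channel.
#' @export
pyramid_channel <- function(pyramid, k) {
  stopifnot(k >= 1, k <= dim(pyramid$channels)[3L])
  pyramid$channels[, , k]
}
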