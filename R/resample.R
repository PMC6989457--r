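# Exact area (box-average) resampling via integral images, and bilinear
# upsampling. The integral image of a piecewise-constant pixel raster is
# piecewise bilinear, so bilinear interpolation of the discrete integral at
# fractional coordinates gives *exact* box integrals with fractional edges.
# This is the anti-aliased sampler used both for glyph resizing (downscale)
# and for the crop pyramid.

# integral image with a zero top row / left column; I[(y+1),(x+1)] = sum M[1:y,1:x]
integral_image <- function(M) {
  H <- nrow(M); W <- ncol(M)
  I <- matrix(0, H + 1L, W + 1L)
  I[-1L, -1L] <- apply(M, 2L, cumsum)
  I[-1L, ] <- t(apply(I[-1L, , drop = FALSE], 1L, cumsum))
  I
}

# evaluate an integral image at continuous coords (exact bilinear, clamped:
# the underlying raster has no mass outside its support)
eval_integral <- function(I, ys, xs) {
  H <- nrow(I) - 1L; W <- ncol(I) - 1L
  ys <- pmin(pmax(ys, 0), H); xs <- pmin(pmax(xs, 0), W)
  y0 <- pmin(floor(ys), H - 1L); fy <- ys - y0
  x0 <- pmin(floor(xs), W - 1L); fx <- xs - x0
  Ry <- I[y0 + 1L, , drop = FALSE] * (1 - fy) + I[y0 + 2L, , drop = FALSE] * fy
  A <- Ry[, x0 + 1L, drop = FALSE]
  B <- Ry[, x0 + 2L, drop = FALSE]
  n <- length(ys)
  A * matrix(1 - fx, n, length(xs), byrow = TRUE) +
    B * matrix(fx, n, length(xs), byrow = TRUE)
}

# mean of M over the uniform box grid with edge vectors ey, ex (continuous
# raster coords, origin at the top-left corner); boxes may extend beyond the
# raster, where the value `bg` fills in.
box_grid_mean <- function(I, ey, ex, bg = 0) {
  S <- eval_integral(I, ey, ex)
  ny <- length(ey); nx <- length(ex)
  D <- S[-1L, -1L, drop = FALSE] - S[-ny, -1L, drop = FALSE] -
    S[-1L, -nx, drop = FALSE] + S[-ny, -nx, drop = FALSE]
  areas <- outer(diff(ey), diff(ex))
  bg + D / areas
}

resize_area <- function(M, out_h, out_w = out_h) {
  I <- integral_image(M)
  ey <- nrow(M) * (0:out_h) / out_h
  ex <- ncol(M) * (0:out_w) / out_w
  box_grid_mean(I, ey, ex, bg = 0)
}

resize_bilinear <- function(M, out_h, out_w = out_h) {
  H <- nrow(M); W <- ncol(M)
  # output pixel centres mapped to input continuous coords, clamped to centres
  yc <- pmin(pmax((seq_len(out_h) - 0.5) * H / out_h, 0.5), H - 0.5)
  xc <- pmin(pmax((seq_len(out_w) - 0.5) * W / out_w, 0.5), W - 0.5)
  y0 <- pmin(floor(yc - 0.5) + 1L, H - 1L); fy <- yc - (y0 - 0.5)
  x0 <- pmin(floor(xc - 0.5) + 1L, W - 1L); fx <- xc - (x0 - 0.5)
  Ry <- M[y0, , drop = FALSE] * (1 - fy) + M[y0 + 1L, , drop = FALSE] * fy
  Ry[, x0, drop = FALSE] * matrix(1 - fx, out_h, out_w, byrow = TRUE) +
    Ry[, x0 + 1L, drop = FALSE] * matrix(fx, out_h, out_w, byrow = TRUE)
}

#' Resample a grayscale raster
#'
#' Area-averaging (anti-aliased) for downscaling, bilinear for upscaling.
#'
#' @param M Numeric matrix.
#' @param out_px Output side in pixels (square output).
#' @param method "auto" (default), "area" or "bilinear".
#' @return `out_px` x `out_px` matrix.
#' @export
resample_image <- function(M, out_px, method = c("auto", "area", "bilinear")) {
  method <- match.arg(method)
  stopifnot(out_px >= 1)
  if (method == "auto") {
    method <- if (out_px < nrow(M)) "area" else "bilinear"
  }
  if (out_px == nrow(M) && out_px == ncol(M)) return(M)
  switch(method,
         area = resize_area(M, out_px),
         bilinear = resize_bilinear(M, out_px))
}
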