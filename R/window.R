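# Invariance windows: (size x eccentricity) accuracy maps, an interpolated
# surface, and threshold-crossing boundaries.

interpolation_error <- function(msg) {
  stop(structure(class = c("foveanet_interpolation_error", "error",
                           "condition"),
                 list(message = msg, call = NULL)))
}

#' Build an invariance window from condition results
#'
#' Stores the measured (size, eccentricity) -> accuracy nodes together with
#' an interpolated surface and, per size, the boundary eccentricity at which
#' the interpolated accuracy crosses a threshold (default 0.85) -- the
#' operational "range of invariance". The surface is separable linear
#' interpolation (along eccentricity within a size, then across sizes); it
#' agrees exactly with the measured accuracies at the nodes. (The display
#' interpolation named for the reference figures, natural neighbour, is not
#' available offline; the linear fallback has identical node values.)
#'
#' @param results Either a data frame with columns `size`, `ecc`, `accuracy`
#'   or a list of `condition_result` objects (eccentricity taken from the
#'   varying side of the regime).
#' @param regime Regime label stored with the window.
#' @param threshold Accuracy threshold defining the invariance boundary.
#' @return An `invariance_window` with `grid` (data frame), `surface`
#'   (function of `(size, ecc)`), `boundaries` (data frame with `size`,
#'   `boundary_ecc`, `censored`), `regime`, `threshold`.
#' @export
build_window <- function(results, regime = "central", threshold = 0.85) {
  grid <- if (is.data.frame(results)) results else {
    do.call(rbind, lapply(results, function(r) {
      s <- r$spec
      ecc <- if (s$regime == "peripheral") abs(s$target_ecc)
             else abs(s$test_ecc)
      size <- if (s$regime == "peripheral") s$target_size else s$test_size
      data.frame(size = size, ecc = ecc, accuracy = r$accuracy)
    }))
  }
  stopifnot(all(c("size", "ecc", "accuracy") %in% names(grid)))
  grid <- grid[order(grid$size, grid$ecc), ]
  if (nrow(grid) < 3L) {
    interpolation_error("need at least 3 grid nodes")
  }
  M <- cbind(grid$size, grid$ecc)
  if (qr(sweep(M, 2L, colMeans(M)))$rank < 2L &&
      length(unique(grid$size)) > 1L && length(unique(grid$ecc)) > 1L) {
    interpolation_error("grid nodes are collinear")
  }
  rows <- split(grid, grid$size)
  sizes <- as.numeric(names(rows))
  row_fun <- lapply(rows, function(r) {
    if (nrow(r) == 1L) {
      function(e) rep(r$accuracy, length(e))
    } else {
      function(e) stats::approx(r$ecc, r$accuracy, xout = e, rule = 2)$y
    }
  })
  surface <- function(size, ecc) {
    vals <- vapply(row_fun, function(f) f(ecc), numeric(length(ecc)))
    vals <- matrix(vals, nrow = length(ecc))
    if (length(sizes) == 1L) return(vals[, 1L])
    vapply(seq_along(ecc), function(i) {
      stats::approx(sizes, vals[i, ], xout = size, rule = 2)$y
    }, numeric(1))
  }
  boundaries <- do.call(rbind, lapply(seq_along(sizes), function(si) {
    r <- rows[[si]]
    ecc <- r$ecc; acc <- r$accuracy
    if (acc[1L] < threshold) {
      b <- ecc[1L]; cens <- FALSE
    } else if (all(acc >= threshold)) {
      b <- max(ecc); cens <- TRUE
    } else {
      j <- which(acc < threshold)[1L]
      b <- ecc[j - 1L] + (threshold - acc[j - 1L]) *
        (ecc[j] - ecc[j - 1L]) / (acc[j] - acc[j - 1L])
      cens <- FALSE
    }
    data.frame(size = sizes[si], boundary_ecc = b, censored = cens)
  }))
  structure(list(grid = grid, surface = surface, boundaries = boundaries,
                 regime = regime, threshold = threshold),
            class = "invariance_window")
}

#' @export
print.invariance_window <- function(x, ...) {
  cat(sprintf("<invariance_window> regime '%s', %d nodes, threshold %.2f\n",
              x$regime, nrow(x$grid), x$threshold))
  print(x$boundaries, row.names = FALSE)
  invisible(x)
}

#' Evaluate the interpolated accuracy surface of a window
#' @param window An `invariance_window`.
#' @param size Size in arcmin (scalar).
#' @param ecc Eccentricities in degrees (vector).
#' @return Interpolated accuracies.
#' @export
window_surface <- function(window, size, ecc) window$surface(size, ecc)

#' Export a window heatmap as a PNG image
#'
#' Uses the base png device when the build supports it.
#'
#' @param window An `invariance_window`.
#' @param path Output file path.
#' @param n_grid Interpolation grid resolution per axis.
#' @return The path, invisibly.
#' @export
plot_window <- function(window, path, n_grid = 60L) {
  if (!capabilities("png")) {
    warning("png device unavailable; skipping heatmap", call. = FALSE)
    return(invisible(path))
  }
  sizes <- seq(min(window$grid$size), max(window$grid$size),
               length.out = n_grid)
  eccs <- seq(min(window$grid$ecc), max(window$grid$ecc),
              length.out = n_grid)
  Z <- vapply(sizes, function(s) window$surface(s, eccs), numeric(n_grid))
  grDevices::png(path, width = 640, height = 520)
  on.exit(grDevices::dev.off())
  graphics::image(eccs, sizes, Z, col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "eccentricity (deg)", ylab = "size (arcmin)",
                  main = sprintf("Window of invariance (%s)", window$regime))
  graphics::contour(eccs, sizes, Z, levels = window$threshold, add = TRUE,
                    lwd = 2)
  graphics::points(window$grid$ecc, window$grid$size, pch = 21, bg = "white")
  invisible(path)
}
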