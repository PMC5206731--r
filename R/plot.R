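## Base-graphics views of alignment fields. Axial vectors are drawn as
## headless segments (a fiber axis has no direction), color-coded by
## alignment length.

.alignPalette <- function(n = 256L)
  grDevices::colorRampPalette(c("#2c7bb6", "#abd9e9", "#ffffbf",
                                "#fdae61", "#d7191c"))(n)

.lengthColor <- function(len, pal = .alignPalette()) {
  idx <- pmax(1L, pmin(length(pal), 1L + floor(len * (length(pal) - 1L))))
  pal[idx]
}

#' Plot a local alignment vector field
#'
#' Quiver-style 2D view of one z-slice: each valid cell is drawn as a
#' headless segment along its axial angle, scaled by its alignment length
#' and color-coded by it (blue = 0 to red = 1); the tumor boundary, if
#' any, is overlaid. The y axis is flipped so the plot matches image
#' display (origin top-left, y down).
#'
#' @param field A [VectorField-class].
#' @param file Optional PNG path; when given the plot is written there.
#' @param scale Segment half-length at alignment 1, in pixels; defaults
#'   to twice the grid spacing.
#' @param ... Passed to [graphics::plot()].
#' @return \code{file} (or \code{NULL}), invisibly.
#' @export
plotField <- function(field, file = NULL, scale = NULL, ...) {
  stopifnot(is(field, "VectorField"))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 900)
    on.exit(grDevices::dev.off())
  }
  g <- field@grid
  if (is.null(scale)) scale <- 2 * g@spacing
  graphics::plot(NA, xlim = c(1, g@imageWidth), ylim = c(g@imageHeight, 1),
                 asp = 1, xlab = "x [px]", ylab = "y [px]",
                 main = sprintf("Local alignment vectors (z = %d)",
                                field@zIndex), ...)
  v <- validCells(field)
  if (nrow(v) > 0L) {
    dx <- scale * v$length * cos(v$angle * .DEG2RAD)
    dy <- scale * v$length * sin(v$angle * .DEG2RAD)
    graphics::segments(v$x - dx, v$y - dy, v$x + dx, v$y + dy,
                       col = .lengthColor(v$length), lwd = 1.5)
  }
  if (!is.null(field@boundary)) {
    th <- seq(0, 2 * pi, length.out = 360L)
    graphics::lines(field@boundary@center[1] + field@boundary@radius * cos(th),
                    field@boundary@center[2] + field@boundary@radius * sin(th),
                    col = "goldenrod", lwd = 2)
  }
  invisible(file)
}

#' 3D view of high-alignment cells of a z-stack
#'
#' Renders the cells whose alignment strictly exceeds \code{threshold}
#' (default 0.8) as points in an orthographic projection of the stack,
#' with the z axis magnified four-fold (the conventional X:Y:Z = 1:1:4
#' display for thin stacks) and colors encoding the alignment length.
#' An empty selection produces an empty, annotated plot.
#'
#' @param stack A [StackField-class].
#' @param threshold Visualization threshold in \eqn{[0, 1]}.
#' @param file Optional PNG path.
#' @param zMagnify z-axis magnification factor (default 4).
#' @param azimuthDeg Projection azimuth in degrees.
#' @param elevationDeg Projection elevation in degrees.
#' @return \code{file} (or \code{NULL}), invisibly.
#' @export
plotStack3D <- function(stack, threshold = 0.8, file = NULL, zMagnify = 4,
                        azimuthDeg = 35, elevationDeg = 25) {
  stopifnot(is(stack, "StackField"))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700)
    on.exit(grDevices::dev.off())
  }
  high <- filterHighAlignment(stack, threshold)
  px <- stack@fields[[1L]]@pixelSize
  az <- azimuthDeg * .DEG2RAD
  el <- elevationDeg * .DEG2RAD
  ## orthographic projection of (x, y, z_magnified) in micrometers
  proj <- function(x, y, z) {
    u <- x * cos(az) - y * sin(az)
    v <- (x * sin(az) + y * cos(az)) * sin(el) + z * cos(el)
    cbind(u, v)
  }
  if (nrow(high) == 0L) {
    graphics::plot(NA, xlim = 0:1, ylim = 0:1, axes = FALSE,
                   xlab = "", ylab = "",
                   main = sprintf("No cells above alignment %g", threshold))
    graphics::box()
    return(invisible(file))
  }
  p <- proj(high$x * px, high$y * px, high$z_um * zMagnify)
  graphics::plot(p[, 1], p[, 2], pch = 16, cex = 0.7, asp = 1,
                 col = .lengthColor(high$length),
                 xlab = "projected x [um]", ylab = "projected y/z [um]",
                 main = sprintf("High-alignment cells (> %g), z x %g",
                                threshold, zMagnify))
  invisible(file)
}
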