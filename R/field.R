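## Local sampling-circle grid and the alignment vector field.
##
## A regular grid of circle centers is laid over the image (default every
## 5 px). Each circle gathers the quantized segments whose midpoints fall
## inside it and, unless excluded, yields one local alignment vector. A
## cell is excluded when its circle crosses the image boundary, when it
## intersects or lies inside the tumor disk, or when it contains too few
## segments; the checks apply in that priority order.

## Grid coordinates along one axis: 1, 1 + s, 1 + 2s, ... <= dim (1-based).
.gridAxis <- function(dim, spacing) {
  seq(1, dim, by = spacing)
}

#' Grid positions of the sampling-circle field
#'
#' Centers of the local sampling circles: 1-based pixel coordinates
#' \code{1 + k * spacing} not exceeding the image dimension, on both axes,
#' in row-major order (y varies slowest). A 512 x 512 image at 5-pixel
#' spacing gives 103 positions per axis, 10,609 in total.
#'
#' @param width,height Image size in pixels.
#' @param spacing Grid spacing in pixels.
#' @return A two-column matrix of \code{(x, y)} positions.
#' @examples
#' nrow(buildGrid(512, 512, 5))  # 10609
#' @export
buildGrid <- function(width, height, spacing) {
  if (length(spacing) != 1L || !is.finite(spacing) || spacing <= 0)
    stop("'spacing' must be a single positive number", call. = FALSE)
  if (width < 1 || height < 1)
    stop("image dimensions must be >= 1 pixel", call. = FALSE)
  xs <- .gridAxis(width, spacing)
  ys <- .gridAxis(height, spacing)
  cbind(x = rep(xs, times = length(ys)), y = rep(ys, each = length(xs)))
}

#' Quantized segments inside a sampling circle
#'
#' Selects the rows of a segment table whose midpoints lie at distance at
#' most \code{radius} from \code{center} (boundary-inclusive). Membership
#' by midpoint keeps every segment's weight whole: a segment is counted by
#' exactly the circles that contain its midpoint.
#'
#' @param segments A segment table (see [quantizeFiber()]).
#' @param center Circle center \code{c(x, y)} in pixels.
#' @param radius Circle radius in pixels.
#' @return The subset of \code{segments} inside the circle.
#' @export
segmentsInCircle <- function(segments, center, radius) {
  if (length(radius) != 1L || !is.finite(radius) || radius <= 0)
    stop("'radius' must be a single positive number", call. = FALSE)
  d2 <- (segments$xm - center[1])^2 + (segments$ym - center[2])^2
  segments[d2 <= radius^2, , drop = FALSE]
}

#' Exclusion status of one grid cell
#'
#' Applies the exclusion rules to a sampling circle of radius
#' \code{grid@circleRadius} centered at \code{position}, in priority
#' order: \code{excluded_image_boundary} if the circle extends beyond the
#' image \eqn{[1, W] \times [1, H]}; else \code{excluded_tumor_boundary}
#' if a boundary is given and the circle intersects or lies inside the
#' tumor disk (center distance \code{< boundary radius + R});
#' else \code{excluded_min_fibers} unless the circle contains strictly
#' more than \code{grid@minFiberCount} segments; else \code{valid}.
#'
#' @param position Circle center \code{c(x, y)}.
#' @param grid A [GridSpec-class].
#' @param boundary A [CircularBoundary-class] or \code{NULL}.
#' @param segmentCount Number of quantized segments inside the circle.
#' @return One of \code{"valid"}, \code{"excluded_image_boundary"},
#'   \code{"excluded_tumor_boundary"}, \code{"excluded_min_fibers"}.
#' @export
classifyCell <- function(position, grid, boundary = NULL, segmentCount = 0L) {
  R <- grid@circleRadius
  x <- position[1]; y <- position[2]
  if (x - R < 1 || x + R > grid@imageWidth ||
      y - R < 1 || y + R > grid@imageHeight)
    return("excluded_image_boundary")
  if (!is.null(boundary)) {
    d <- sqrt((x - boundary@center[1])^2 + (y - boundary@center[2])^2)
    if (d < boundary@radius + R)
      return("excluded_tumor_boundary")
  }
  if (segmentCount <= grid@minFiberCount)
    return("excluded_min_fibers")
  "valid"
}

#' Compute the local alignment vector field of one z-slice
#'
#' For every grid position: gather the quantized segments whose midpoints
#' lie inside the sampling circle, classify the cell (see
#' [classifyCell()]), and for valid cells compute the alignment vector of
#' the gathered segment angles. Deterministic given its inputs.
#'
#' @param segments A segment table for one z-slice (see
#'   [quantizeFibers()]).
#' @param grid A [GridSpec-class].
#' @param boundary A [CircularBoundary-class] or \code{NULL}.
#' @param zIndex z-slice index stored on the field.
#' @param zSpacing,pixelSize Physical calibration in micrometers.
#' @return A [VectorField-class].
#' @examples
#' seg <- quantizeFibers(straightFiberTable(10, 50, 90, 50))
#' fld <- computeField(seg, gridSpec(100, 100, minFiberCount = 0))
#' @export
computeField <- function(segments, grid, boundary = NULL, zIndex = 1L,
                         zSpacing = 1, pixelSize = 0.83) {
  stopifnot(is(grid, "GridSpec"))
  pos <- buildGrid(grid@imageWidth, grid@imageHeight, grid@spacing)
  n <- nrow(pos)
  R <- grid@circleRadius
  status <- character(n)
  len <- ang <- rep(NA_real_, n)
  cnt <- integer(n)
  for (i in seq_len(n)) {
    d2 <- (segments$xm - pos[i, 1])^2 + (segments$ym - pos[i, 2])^2
    inside <- which(d2 <= R^2)
    cnt[i] <- length(inside)
    status[i] <- classifyCell(pos[i, ], grid, boundary, cnt[i])
    if (status[i] == "valid") {
      v <- alignmentVector(segments$angle[inside])
      len[i] <- v@length
      ang[i] <- v@angle
    }
  }
  cells <- data.frame(x = pos[, 1], y = pos[, 2], status = status,
                      length = len, angle = ang, n_segments = cnt)
  new("VectorField", grid = grid, cells = cells, boundary = boundary,
      zIndex = as.integer(zIndex), zSpacing = as.numeric(zSpacing),
      pixelSize = as.numeric(pixelSize))
}

#' Global alignment vector of a segment set
#'
#' The alignment vector over all quantized segments at once — the
#' whole-image statistic the local field refines. In heterogeneous
#' patterns (e.g. fibers radiating from a boundary) the global vector
#' averages out opposing orientations and under-reports alignment, which
#' is the motivation for the local sampling circles.
#'
#' @param segments A non-empty segment table.
#' @return An [AlignmentVector-class] with no position.
#' @export
globalAlignment <- function(segments) {
  if (nrow(segments) == 0L)
    stop("cannot compute a global alignment vector of zero segments",
         call. = FALSE)
  alignmentVector(segments$angle)
}

#' @describeIn cells Per-cell table of a field: position, status,
#'   alignment length, axial angle and segment count.
#' @param x A [VectorField-class] or [StackField-class].
#' @export
setMethod("cells", "VectorField", function(x) x@cells)

#' @describeIn cells Pooled per-cell table over all z-slices, with a
#'   \code{z_index} column.
#' @export
setMethod("cells", "StackField", function(x) {
  out <- do.call(rbind, lapply(x@fields, function(f)
    cbind(f@cells, z_index = f@zIndex)))
  rownames(out) <- NULL
  out
})

#' @describeIn validCells Valid cells of one slice.
#' @param x A [VectorField-class] or [StackField-class].
#' @export
setMethod("validCells", "VectorField", function(x)
  x@cells[x@cells$status == "valid", , drop = FALSE])

#' @describeIn validCells Valid cells pooled over the z-stack.
#' @export
setMethod("validCells", "StackField", function(x) {
  out <- cells(x)
  out[out$status == "valid", , drop = FALSE]
})

#' Cell tables of alignment fields
#'
#' \code{cells} returns the full per-cell table (one row per grid
#' position); \code{validCells} restricts it to cells with a defined
#' alignment vector.
#'
#' @name cells
NULL

#' @name validCells
#' @rdname cells
NULL
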