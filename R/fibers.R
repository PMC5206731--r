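## Fiber polylines and fixed-arclength quantization.
##
## Fibers arrive as polylines (ordered vertex lists in pixel coordinates),
## the native output shape of curvelet-based fiber extraction. The package
## keeps them in a plain "fiber table": one row per vertex with columns
## fiber_id, z_index, vertex_index, x, y. Coordinates are continuous
## (sub-pixel allowed); the raster convention is 1-based with the origin at
## the image's top-left, x rightward and y downward. Axial angles are
## atan2(dy, dx) reduced modulo 180, so with y pointing down the angle runs
## clockwise on screen; "vertical" is 90 degrees either way, and axial
## statistics are insensitive to the flip.

.FIBER_COLS <- c("fiber_id", "z_index", "vertex_index", "x", "y")

#' Validate a fiber table
#'
#' Checks the tabular fiber representation used throughout the package:
#' a \code{data.frame} with columns \code{fiber_id}, \code{z_index},
#' \code{vertex_index}, \code{x}, \code{y}, one row per polyline vertex.
#' Every fiber must have at least two vertices with finite coordinates.
#'
#' @param fibers A fiber table.
#' @param allowEmpty Accept a table with zero rows.
#' @return The table, invisibly; errors name the offending records.
#' @export
checkFiberTable <- function(fibers, allowEmpty = TRUE) {
  if (!is.data.frame(fibers))
    stop("fiber table must be a data.frame", call. = FALSE)
  missing <- setdiff(.FIBER_COLS, names(fibers))
  if (length(missing))
    stop("fiber table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(fibers) == 0L) {
    if (!allowEmpty) stop("fiber table is empty", call. = FALSE)
    return(invisible(fibers))
  }
  bad <- which(!is.finite(fibers$x) | !is.finite(fibers$y))
  if (length(bad))
    stop("non-finite coordinates in fiber table row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  key <- paste(fibers$z_index, fibers$fiber_id, sep = "\r")
  nv <- table(key)
  short <- names(nv)[nv < 2L]
  if (length(short)) {
    ids <- vapply(strsplit(short, "\r", fixed = TRUE), `[`, character(1), 2L)
    stop("fiber(s) with fewer than 2 vertices: ",
         paste(utils::head(ids, 5L), collapse = ", "), call. = FALSE)
  }
  invisible(fibers)
}

#' Build a fiber table from straight fibers
#'
#' Convenience constructor for two-vertex (straight) fibers, the shape the
#' simulators emit.
#'
#' @param x1,y1,x2,y2 Endpoint coordinate vectors, one entry per fiber.
#' @param zIndex z-slice index (recycled).
#' @param fiberId Fiber identifiers; defaults to \code{1:n}.
#' @return A fiber table (see [checkFiberTable()]).
#' @export
straightFiberTable <- function(x1, y1, x2, y2, zIndex = 1L,
                               fiberId = seq_along(x1)) {
  n <- length(x1)
  data.frame(
    fiber_id = rep(fiberId, each = 2L),
    z_index = rep(as.integer(zIndex), length.out = 2L * n),
    vertex_index = rep(1:2, times = n),
    x = as.numeric(rbind(x1, x2)),
    y = as.numeric(rbind(y1, y2)))
}

#' Axial angle of a straight segment
#'
#' Angle of the chord from \code{p1} to \code{p2}, reduced modulo 180 into
#' \eqn{[0, 180)} degrees. Reversing the endpoints gives the same axial
#' angle.
#'
#' @param p1,p2 Points as \code{c(x, y)} or two-column matrices.
#' @return Axial angle(s) in degrees.
#' @examples
#' segmentAngle(c(0, 0), c(1, 1))  # 45
#' segmentAngle(c(1, 1), c(0, 0))  # 45
#' @export
segmentAngle <- function(p1, p2) {
  p1 <- rbind(p1); p2 <- rbind(p2)
  dx <- p2[, 1] - p1[, 1]
  dy <- p2[, 2] - p1[, 2]
  if (any(dx == 0 & dy == 0))
    stop("degenerate segment: coincident endpoints", call. = FALSE)
  unname(.mod180(atan2(dy, dx) / .DEG2RAD))
}

#' Arclength of a polyline
#'
#' @param vertices Two-column matrix of ordered \code{(x, y)} vertices.
#' @return Total arclength (sum of consecutive vertex distances).
#' @export
fiberArclength <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 2L)
    stop("a fiber needs at least 2 vertices", call. = FALSE)
  sum(sqrt(rowSums(diff(vertices)^2)))
}

## Interpolate points at given arclengths along a polyline.
.arclengthPoints <- function(vertices, s) {
  seglen <- sqrt(rowSums(diff(vertices)^2))
  cum <- c(0, cumsum(seglen))
  ## approx() handles duplicate knots (zero-length edges) via ties
  ## rule = 2 clamps sample arclengths that exceed the total by a rounding
  ## epsilon (the count guard in quantizeFiber admits exact multiples)
  x <- stats::approx(cum, vertices[, 1], xout = s, ties = "ordered",
                     rule = 2)$y
  y <- stats::approx(cum, vertices[, 2], xout = s, ties = "ordered",
                     rule = 2)$y
  cbind(x, y)
}

#' Quantize one fiber into fixed-arclength segments
#'
#' Walks the polyline by arclength and cuts it at multiples of the
#' filtering length \code{L}: sample points sit at arclengths
#' \eqn{0, L, 2L, \ldots} (linear interpolation within polyline edges) and
#' each quantized segment is the straight chord between consecutive
#' samples. A trailing remainder shorter than \code{L} is dropped, so the
#' segment count is \code{floor(arclength / L)} and every segment carries
#' equal weight; fibers shorter than \code{L} yield no segments (this is
#' the extraction-noise filter). For curved paths the chord is at most
#' \code{L} long while its arclength step is exactly \code{L}.
#'
#' @param vertices Two-column matrix of ordered \code{(x, y)} vertices.
#' @param filterLength Filtering length \code{L} in pixels (default 5).
#' @param fiberId,zIndex Identifiers copied onto the output rows.
#' @return A segment table: \code{data.frame} with columns
#'   \code{fiber_id}, \code{z_index}, \code{seg_index}, \code{x1},
#'   \code{y1}, \code{x2}, \code{y2}, \code{xm}, \code{ym} (midpoint) and
#'   \code{angle} (axial, degrees).
#' @examples
#' v <- cbind(c(0, 40), c(0, 0))
#' nrow(quantizeFiber(v, 5))  # 8
#' @export
quantizeFiber <- function(vertices, filterLength = 5, fiberId = 1L,
                          zIndex = 1L) {
  if (length(filterLength) != 1L || !is.finite(filterLength) ||
      filterLength <= 0)
    stop("'filterLength' must be a single positive number", call. = FALSE)
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 2L || ncol(vertices) != 2L)
    stop("'vertices' must be an n x 2 matrix with n >= 2", call. = FALSE)
  if (!all(is.finite(vertices)))
    stop("fiber vertices must be finite", call. = FALSE)
  total <- fiberArclength(vertices)
  n <- floor(total / filterLength + 1e-9)  # guard exact multiples
  if (n < 1L) return(.emptySegments())
  pts <- .arclengthPoints(vertices, (0:n) * filterLength)
  p1 <- pts[-(n + 1L), , drop = FALSE]
  p2 <- pts[-1L, , drop = FALSE]
  data.frame(
    fiber_id = rep(fiberId, n), z_index = rep(as.integer(zIndex), n),
    seg_index = seq_len(n),
    x1 = p1[, 1], y1 = p1[, 2], x2 = p2[, 1], y2 = p2[, 2],
    xm = (p1[, 1] + p2[, 1]) / 2, ym = (p1[, 2] + p2[, 2]) / 2,
    angle = segmentAngle(p1, p2))
}

.emptySegments <- function() {
  data.frame(fiber_id = character(0), z_index = integer(0),
             seg_index = integer(0), x1 = numeric(0), y1 = numeric(0),
             x2 = numeric(0), y2 = numeric(0), xm = numeric(0),
             ym = numeric(0), angle = numeric(0))
}

#' Quantize all fibers of a fiber table
#'
#' Applies [quantizeFiber()] to every fiber of a fiber table, z-slice by
#' z-slice. Output rows are ordered by z-index, then fiber id, then
#' position along the fiber.
#'
#' @param fibers A fiber table (see [checkFiberTable()]).
#' @param filterLength Filtering length in pixels (default 5).
#' @return A segment table (see [quantizeFiber()]); zero rows if no fiber
#'   reaches the filtering length.
#' @examples
#' ft <- straightFiberTable(0, 0, 40, 0)
#' nrow(quantizeFibers(ft, 5))  # 8
#' @export
quantizeFibers <- function(fibers, filterLength = 5) {
  checkFiberTable(fibers)
  if (nrow(fibers) == 0L) return(.emptySegments())
  ord <- order(fibers$z_index, fibers$fiber_id, fibers$vertex_index)
  fibers <- fibers[ord, , drop = FALSE]
  key <- paste(fibers$z_index, fibers$fiber_id, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(fibers)), factor(key, unique(key))),
                   function(idx) {
    quantizeFiber(cbind(fibers$x[idx], fibers$y[idx]), filterLength,
                  fiberId = fibers$fiber_id[idx[1L]],
                  zIndex = fibers$z_index[idx[1L]])
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
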