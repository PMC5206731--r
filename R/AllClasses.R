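#' @import methods
NULL

## Cell exclusion statuses, in priority order (image boundary checked first,
## then tumor boundary, then minimum segment count).
.CELL_STATUSES <- c("valid", "excluded_image_boundary",
                    "excluded_tumor_boundary", "excluded_min_fibers")

#' AlignmentVector: an axial alignment vector
#'
#' The alignment vector of a set of axial angles: fiber angles in
#' \eqn{[0, 180)} degrees are doubled onto the circle, the mean resultant
#' vector (MRV) of the corresponding unit vectors is formed, and the MRV
#' angle is halved back to the axial range. The length lies in \eqn{[0, 1]}
#' (1 = perfectly aligned, 0 = no net alignment) and equals the 2D nematic
#' orientational order parameter of the same angle set. The axial angle is
#' \code{NA} when the length is zero (direction undefined).
#'
#' @slot length Alignment vector length, dimensionless in \eqn{[0, 1]}.
#' @slot angle Axial angle in degrees, \eqn{[0, 180)}; \code{NA} when
#'   \code{length} is 0.
#' @slot nSegments Number of contributing quantized segments (or fibers).
#' @slot position Grid position in pixel coordinates, \code{numeric(2)} or
#'   \code{numeric(0)} for a global vector.
#'
#' @seealso [alignmentVector()], [globalAlignment()]
#' @export
setClass("AlignmentVector",
  representation(length = "numeric", angle = "numeric",
                 nSegments = "integer", position = "numeric"),
  prototype(length = NA_real_, angle = NA_real_, nSegments = 0L,
            position = numeric(0)),
  validity = function(object) {
    msg <- NULL
    if (length(object@length) != 1L || !is.finite(object@length))
      msg <- c(msg, "'length' must be a single finite number")
    else if (object@length < 0 || object@length > 1)
      msg <- c(msg, "'length' must lie in [0, 1]")
    if (length(object@angle) != 1L)
      msg <- c(msg, "'angle' must be a single number (possibly NA)")
    else if (!is.na(object@angle) && (object@angle < 0 || object@angle >= 180))
      msg <- c(msg, "'angle' must lie in [0, 180)")
    if (length(object@length) == 1L && is.finite(object@length)) {
      if (object@length == 0 && !is.na(object@angle))
        msg <- c(msg, "'angle' must be NA when length is 0")
      if (object@length > 0 && is.na(object@angle))
        msg <- c(msg, "'angle' must be defined when length > 0")
    }
    if (length(object@nSegments) != 1L || is.na(object@nSegments) ||
        object@nSegments < 0L)
      msg <- c(msg, "'nSegments' must be a single non-negative integer")
    if (!length(object@position) %in% c(0L, 2L))
      msg <- c(msg, "'position' must be numeric(0) or numeric(2)")
    if (is.null(msg)) TRUE else msg
  })

#' CircularBoundary: a circular exclusion boundary
#'
#' A circular (tumor) boundary in pixel coordinates. Local sampling circles
#' that intersect the disk, or lie inside it, are excluded from the
#' alignment field.
#'
#' @slot center Center \code{(x, y)} in pixels.
#' @slot radius Radius in pixels, \eqn{> 0}.
#'
#' @export
setClass("CircularBoundary",
  representation(center = "numeric", radius = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@center) != 2L || !all(is.finite(object@center)))
      msg <- c(msg, "'center' must be two finite coordinates")
    if (length(object@radius) != 1L || !is.finite(object@radius) ||
        object@radius <= 0)
      msg <- c(msg, "'radius' must be a single positive number")
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn CircularBoundary-class Constructor.
#' @param center Center \code{(x, y)} in pixels.
#' @param radius Radius in pixels.
#' @return A \code{CircularBoundary}.
#' @examples
#' circularBoundary(c(0, 0), 150)
#' @export
circularBoundary <- function(center, radius) {
  new("CircularBoundary", center = as.numeric(center),
      radius = as.numeric(radius))
}

#' GridSpec: sampling-circle grid specification
#'
#' Geometry of the local sampling-circle grid laid over one image: image
#' size, grid spacing, sampling-circle radius and the minimum quantized
#' segment count a circle must (strictly) exceed to yield a valid vector.
#'
#' @slot imageWidth,imageHeight Image size in pixels.
#' @slot spacing Grid spacing in pixels (default convention: 5).
#' @slot circleRadius Sampling-circle radius in pixels.
#' @slot minFiberCount Minimum segment count \code{F}; a cell is valid only
#'   when its circle contains more than \code{F} segments (strict
#'   inequality).
#'
#' @export
setClass("GridSpec",
  representation(imageWidth = "numeric", imageHeight = "numeric",
                 spacing = "numeric", circleRadius = "numeric",
                 minFiberCount = "integer"),
  validity = function(object) {
    msg <- NULL
    for (nm in c("imageWidth", "imageHeight", "spacing", "circleRadius")) {
      v <- slot(object, nm)
      if (length(v) != 1L || !is.finite(v) || v <= 0)
        msg <- c(msg, sprintf("'%s' must be a single positive number", nm))
    }
    if (length(object@imageWidth) == 1L && is.finite(object@imageWidth) &&
        object@imageWidth < 1)
      msg <- c(msg, "'imageWidth' must be >= 1")
    if (length(object@minFiberCount) != 1L || is.na(object@minFiberCount) ||
        object@minFiberCount < 0L)
      msg <- c(msg, "'minFiberCount' must be a single integer >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn GridSpec-class Constructor.
#' @param imageWidth,imageHeight Image size in pixels.
#' @param spacing Grid spacing in pixels.
#' @param circleRadius Sampling-circle radius in pixels.
#' @param minFiberCount Minimum segment count (strictly exceeded for a
#'   valid cell).
#' @return A \code{GridSpec}.
#' @examples
#' gridSpec(512, 512)
#' @export
gridSpec <- function(imageWidth, imageHeight, spacing = 5,
                     circleRadius = 25, minFiberCount = 10) {
  new("GridSpec", imageWidth = as.numeric(imageWidth),
      imageHeight = as.numeric(imageHeight), spacing = as.numeric(spacing),
      circleRadius = as.numeric(circleRadius),
      minFiberCount = as.integer(minFiberCount))
}

setClassUnion("CircularBoundaryOrNULL", c("CircularBoundary", "NULL"))

#' VectorField: local alignment vectors of one z-slice
#'
#' The grid of local alignment vectors computed for one image (z-slice).
#' Each grid cell carries an exclusion status (\code{valid},
#' \code{excluded_image_boundary}, \code{excluded_tumor_boundary} or
#' \code{excluded_min_fibers}) and, when valid, an alignment length, axial
#' angle and contributing segment count.
#'
#' @slot grid The [GridSpec-class] used.
#' @slot cells A \code{data.frame} with one row per grid position, columns
#'   \code{x}, \code{y} (pixels), \code{status}, \code{length},
#'   \code{angle} (degrees, \code{NA} unless valid with nonzero length),
#'   \code{n_segments}.
#' @slot boundary The [CircularBoundary-class] applied, or \code{NULL}.
#' @slot zIndex Integer z-slice index.
#' @slot zSpacing Slice spacing in micrometers.
#' @slot pixelSize Pixel size in micrometers.
#'
#' @seealso [computeField()], [cells()], [validCells()]
#' @export
setClass("VectorField",
  representation(grid = "GridSpec", cells = "data.frame",
                 boundary = "CircularBoundaryOrNULL", zIndex = "integer",
                 zSpacing = "numeric", pixelSize = "numeric"),
  validity = function(object) {
    msg <- NULL
    need <- c("x", "y", "status", "length", "angle", "n_segments")
    if (!all(need %in% names(object@cells)))
      msg <- c(msg, paste("'cells' must have columns",
                          paste(need, collapse = ", ")))
    else {
      if (!all(object@cells$status %in% .CELL_STATUSES))
        msg <- c(msg, "unknown cell status")
      valid <- object@cells$status == "valid"
      if (any(valid & is.na(object@cells$length)))
        msg <- c(msg, "valid cells must carry an alignment length")
      if (any(!valid & !is.na(object@cells$length)))
        msg <- c(msg, "excluded cells must not carry an alignment length")
      nx <- .gridAxis(object@grid@imageWidth, object@grid@spacing)
      ny <- .gridAxis(object@grid@imageHeight, object@grid@spacing)
      if (nrow(object@cells) != length(nx) * length(ny))
        msg <- c(msg, "cell count must equal nx * ny of the grid")
    }
    if (length(object@zIndex) != 1L || is.na(object@zIndex))
      msg <- c(msg, "'zIndex' must be a single integer")
    if (is.null(msg)) TRUE else msg
  })

#' StackField: alignment fields of a z-stack
#'
#' An ordered collection of [VectorField-class] objects, one per z-slice,
#' sharing the same grid and pixel size. Summary statistics (alignment
#' distribution, mean alignment, strong-alignment ratio) pool the valid
#' cells of all slices with equal weight.
#'
#' @slot fields List of \code{VectorField}, ordered by \code{zIndex}.
#'
#' @seealso [stackField()], [alignmentDistribution()],
#'   [strongAlignmentRatio()]
#' @export
setClass("StackField",
  representation(fields = "list"),
  validity = function(object) {
    if (length(object@fields) == 0L)
      return("a StackField needs at least one VectorField")
    if (!all(vapply(object@fields, is, logical(1), "VectorField")))
      return("'fields' must all be VectorField objects")
    g1 <- object@fields[[1L]]@grid
    px <- object@fields[[1L]]@pixelSize
    same <- vapply(object@fields, function(f)
      identical(f@grid, g1) && identical(f@pixelSize, px), logical(1))
    if (!all(same))
      return("all fields must share the same GridSpec and pixelSize")
    z <- vapply(object@fields, function(f) f@zIndex, integer(1))
    if (is.unsorted(z, strictly = TRUE))
      return("fields must be strictly ordered by zIndex")
    TRUE
  })

#' @describeIn StackField-class Constructor; sorts the fields by z-index.
#' @param fields A list of \code{VectorField} objects (or a single one).
#' @return A \code{StackField}.
#' @export
stackField <- function(fields) {
  if (is(fields, "VectorField")) fields <- list(fields)
  z <- vapply(fields, function(f) f@zIndex, integer(1))
  new("StackField", fields = fields[order(z)])
}

#' AnalysisConfig: end-to-end analysis parameters
#'
#' All tunable parameters of the fiber-alignment pipeline, with the default
#' working point: 5-pixel filtering length, 5-pixel grid spacing, 25-pixel
#' sampling circles, minimum segment count 10, strong-alignment threshold
#' 0.7, visualization threshold 0.8, 0.83 um pixels, 1 um z-spacing and
#' 0.05-wide alignment histogram bins.
#'
#' @slot filterLength Quantization (filtering) length in pixels.
#' @slot spacing Grid spacing in pixels.
#' @slot circleRadius Sampling-circle radius in pixels.
#' @slot minFiberCount Minimum quantized-segment count (strict).
#' @slot strongThreshold Alignment threshold for the strong-alignment ratio.
#' @slot vizThreshold Alignment threshold for 3D visualization.
#' @slot pixelSize Pixel size in micrometers.
#' @slot zSpacing z-slice spacing in micrometers.
#' @slot binWidth Histogram bin width for alignment distributions.
#'
#' @export
setClass("AnalysisConfig",
  representation(filterLength = "numeric", spacing = "numeric",
                 circleRadius = "numeric", minFiberCount = "integer",
                 strongThreshold = "numeric", vizThreshold = "numeric",
                 pixelSize = "numeric", zSpacing = "numeric",
                 binWidth = "numeric"),
  prototype(filterLength = 5, spacing = 5, circleRadius = 25,
            minFiberCount = 10L, strongThreshold = 0.7, vizThreshold = 0.8,
            pixelSize = 0.83, zSpacing = 1, binWidth = 0.05),
  validity = function(object) {
    msg <- NULL
    for (nm in c("filterLength", "spacing", "circleRadius", "pixelSize",
                 "zSpacing", "binWidth")) {
      v <- slot(object, nm)
      if (length(v) != 1L || !is.finite(v) || v <= 0)
        msg <- c(msg, sprintf("'%s' must be a single positive number", nm))
    }
    for (nm in c("strongThreshold", "vizThreshold")) {
      v <- slot(object, nm)
      if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
        msg <- c(msg, sprintf("'%s' must lie in [0, 1]", nm))
    }
    if (length(object@minFiberCount) != 1L || is.na(object@minFiberCount) ||
        object@minFiberCount < 0L)
      msg <- c(msg, "'minFiberCount' must be a single integer >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn AnalysisConfig-class Constructor with the default working
#'   point; any parameter can be overridden by name.
#' @param filterLength,spacing,circleRadius,minFiberCount Grid and
#'   quantization parameters (pixels / count).
#' @param strongThreshold,vizThreshold,binWidth Dimensionless statistics
#'   parameters.
#' @param pixelSize,zSpacing Physical calibration in micrometers.
#' @return An \code{AnalysisConfig}.
#' @examples
#' analysisConfig(circleRadius = 35)
#' @export
analysisConfig <- function(filterLength = 5, spacing = 5, circleRadius = 25,
                           minFiberCount = 10, strongThreshold = 0.7,
                           vizThreshold = 0.8, pixelSize = 0.83,
                           zSpacing = 1, binWidth = 0.05) {
  new("AnalysisConfig", filterLength = as.numeric(filterLength),
      spacing = as.numeric(spacing), circleRadius = as.numeric(circleRadius),
      minFiberCount = as.integer(minFiberCount),
      strongThreshold = as.numeric(strongThreshold),
      vizThreshold = as.numeric(vizThreshold),
      pixelSize = as.numeric(pixelSize), zSpacing = as.numeric(zSpacing),
      binWidth = as.numeric(binWidth))
}

#' UniformSimConfig: homogeneous in-silico fiber field
#'
#' Configuration for the homogeneous simulator: straight fibers placed
#' uniformly in a square box, all at a common base orientation perturbed by
#' Gaussian angular noise.
#'
#' @slot boxSize Side of the square simulation box, pixels.
#' @slot nFibers Number of fibers.
#' @slot fiberLength Fiber length in pixels.
#' @slot baseAngle Base axial angle in degrees, \eqn{[0, 180)}.
#' @slot noiseStd Standard deviation of the Gaussian angular perturbation,
#'   degrees.
#' @slot seed Integer RNG seed; fully determines the fiber set.
#'
#' @seealso [simulateUniform()]
#' @export
setClass("UniformSimConfig",
  representation(boxSize = "numeric", nFibers = "integer",
                 fiberLength = "numeric", baseAngle = "numeric",
                 noiseStd = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@nFibers < 1L) msg <- c(msg, "'nFibers' must be >= 1")
    if (object@fiberLength <= 0 || object@fiberLength > object@boxSize)
      msg <- c(msg, "'fiberLength' must lie in (0, boxSize]")
    if (object@baseAngle < 0 || object@baseAngle >= 180)
      msg <- c(msg, "'baseAngle' must lie in [0, 180)")
    if (object@noiseStd < 0) msg <- c(msg, "'noiseStd' must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn UniformSimConfig-class Constructor with the standard
#'   validation box: 100 fibers of length 40 in a 512 x 512 box at base
#'   angle 90 degrees.
#' @param boxSize,nFibers,fiberLength,baseAngle,noiseStd,seed See slots.
#' @return A \code{UniformSimConfig}.
#' @export
uniformSimConfig <- function(boxSize = 512, nFibers = 100, fiberLength = 40,
                             baseAngle = 90, noiseStd = 0, seed = 1) {
  new("UniformSimConfig", boxSize = as.numeric(boxSize),
      nFibers = as.integer(nFibers), fiberLength = as.numeric(fiberLength),
      baseAngle = as.numeric(baseAngle), noiseStd = as.numeric(noiseStd),
      seed = as.integer(seed))
}

#' RadialSimConfig: radially aligned fibers around a circular boundary
#'
#' Configuration for the heterogeneous simulator: straight fibers placed
#' around a quarter-disk (tumor) boundary anchored at the box origin,
#' oriented along the radial direction from the boundary center and
#' perturbed by Gaussian angular noise. Fiber midpoints are drawn uniformly
#' from the quarter annulus between the boundary radius and \code{outerRadius}
#' (the global sampling circle, default the box size), clipped to the box.
#'
#' @slot boxSize Side of the square simulation box, pixels.
#' @slot nFibers Number of fibers.
#' @slot fiberLength Fiber length in pixels.
#' @slot boundary The [CircularBoundary-class]; its center must sit at the
#'   box origin corner \code{(0, 0)}.
#' @slot outerRadius Outer placement radius in pixels.
#' @slot noiseStd Gaussian angular noise, degrees.
#' @slot seed Integer RNG seed.
#'
#' @seealso [simulateRadial()]
#' @export
setClass("RadialSimConfig",
  representation(boxSize = "numeric", nFibers = "integer",
                 fiberLength = "numeric", boundary = "CircularBoundary",
                 outerRadius = "numeric", noiseStd = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@nFibers < 1L) msg <- c(msg, "'nFibers' must be >= 1")
    if (object@fiberLength <= 0)
      msg <- c(msg, "'fiberLength' must be positive")
    if (!isTRUE(all.equal(object@boundary@center, c(0, 0))))
      msg <- c(msg, "'boundary' center must sit at the box corner (0, 0)")
    if (object@boundary@radius + object@fiberLength >=
        sqrt(2) * object@boxSize)
      msg <- c(msg, "boundary radius + fiber length must fit the box diagonal")
    if (object@outerRadius <= object@boundary@radius)
      msg <- c(msg, "'outerRadius' must exceed the boundary radius")
    if (object@noiseStd < 0) msg <- c(msg, "'noiseStd' must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn RadialSimConfig-class Constructor with the standard
#'   heterogeneous box: 500 fibers of length 40 in a 512 x 512 box around a
#'   quarter-disk boundary of radius 150 at the origin corner.
#' @param boxSize,nFibers,fiberLength,noiseStd,seed See slots.
#' @param boundaryRadius Tumor quarter-disk radius in pixels.
#' @param outerRadius Outer placement radius; defaults to \code{boxSize}.
#' @return A \code{RadialSimConfig}.
#' @export
radialSimConfig <- function(boxSize = 512, nFibers = 500, fiberLength = 40,
                            boundaryRadius = 150, outerRadius = boxSize,
                            noiseStd = 0, seed = 1) {
  new("RadialSimConfig", boxSize = as.numeric(boxSize),
      nFibers = as.integer(nFibers), fiberLength = as.numeric(fiberLength),
      boundary = circularBoundary(c(0, 0), boundaryRadius),
      outerRadius = as.numeric(outerRadius), noiseStd = as.numeric(noiseStd),
      seed = as.integer(seed))
}

setMethod("show", "AlignmentVector", function(object) {
  cat("AlignmentVector: length", format(object@length, digits = 4))
  if (!is.na(object@angle))
    cat(", axial angle", format(object@angle, digits = 4), "deg")
  else
    cat(", axial angle undefined")
  cat(" (", object@nSegments, " segments", sep = "")
  if (length(object@position) == 2L)
    cat(sprintf(", at x=%g y=%g", object@position[1], object@position[2]))
  cat(")\n")
})

setMethod("show", "VectorField", function(object) {
  tab <- table(factor(object@cells$status, levels = .CELL_STATUSES))
  cat(sprintf("VectorField (z = %d): %d x %d px image, spacing %g px, R = %g px\n",
              object@zIndex, object@grid@imageWidth,
              object@grid@imageHeight, object@grid@spacing,
              object@grid@circleRadius))
  cat(sprintf("  %d cells: %d valid, %d image-boundary, %d tumor-boundary, %d below min count\n",
              nrow(object@cells), tab[["valid"]],
              tab[["excluded_image_boundary"]],
              tab[["excluded_tumor_boundary"]],
              tab[["excluded_min_fibers"]]))
})

setMethod("show", "StackField", function(object) {
  nval <- sum(vapply(object@fields,
                     function(f) sum(f@cells$status == "valid"), numeric(1)))
  cat(sprintf("StackField: %d z-slices, %d valid cells pooled\n",
              length(object@fields), nval))
})

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig:\n")
  cat(sprintf("  filterLength %g px, spacing %g px, circleRadius %g px, minFiberCount %d\n",
              object@filterLength, object@spacing, object@circleRadius,
              object@minFiberCount))
  cat(sprintf("  strongThreshold %g, vizThreshold %g, binWidth %g\n",
              object@strongThreshold, object@vizThreshold, object@binWidth))
  cat(sprintf("  pixelSize %g um, zSpacing %g um\n",
              object@pixelSize, object@zSpacing))
})
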