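## Summary statistics over the valid cells of an alignment field or stack.

.validLengths <- function(x) {
  v <- validCells(x)
  if (nrow(v) == 0L)
    stop("no valid cells: statistics over an empty field are undefined",
         call. = FALSE)
  v$length
}

.distribution <- function(lengths, binWidth) {
  if (length(binWidth) != 1L || !is.finite(binWidth) || binWidth <= 0 ||
      binWidth > 1)
    stop("'binWidth' must lie in (0, 1]", call. = FALSE)
  edges <- seq(0, 1, by = binWidth)
  if (edges[length(edges)] < 1) edges <- c(edges, 1)
  nb <- length(edges) - 1L
  ## left-closed bins, top bin closed on both sides so length 1 is counted
  idx <- pmin(findInterval(lengths, edges, rightmost.closed = TRUE), nb)
  counts <- tabulate(idx, nbins = nb)
  widths <- diff(edges)
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
             count = counts,
             density = counts / (sum(counts) * widths))
}

#' @describeIn alignmentDistribution Distribution for one z-slice.
#' @param x A [VectorField-class] or [StackField-class].
#' @param binWidth Histogram bin width (default 0.05).
#' @export
setMethod("alignmentDistribution", "VectorField", function(x, binWidth = 0.05)
  .distribution(.validLengths(x), binWidth))

#' @describeIn alignmentDistribution Distribution pooled over all z-slices
#'   with equal cell weight.
#' @export
setMethod("alignmentDistribution", "StackField", function(x, binWidth = 0.05)
  .distribution(.validLengths(x), binWidth))

#' Normalized distribution of local alignment values
#'
#' Histogram of the alignment lengths of all valid cells, normalized so
#' that \eqn{\sum_b \mathrm{density}_b \cdot \mathrm{width}_b = 1}. Bins
#' are left-closed on \eqn{[0, 1]}; the top bin also includes 1. Errors if
#' the field has no valid cells.
#'
#' @return A \code{data.frame} with columns \code{bin_lo}, \code{bin_hi},
#'   \code{count}, \code{density}.
#' @name alignmentDistribution
NULL

#' @describeIn meanAlignment Mean over the valid cells of one slice.
#' @param x A [VectorField-class] or [StackField-class].
#' @export
setMethod("meanAlignment", "VectorField", function(x)
  mean(.validLengths(x)))

#' @describeIn meanAlignment Mean over valid cells pooled across z.
#' @export
setMethod("meanAlignment", "StackField", function(x)
  mean(.validLengths(x)))

#' Mean local alignment
#'
#' Arithmetic mean of the alignment lengths of all valid cells; the scalar
#' summary used to track the shift of the alignment distribution over time
#' or between conditions. Errors if there are no valid cells.
#'
#' @return A number in \eqn{[0, 1]}.
#' @name meanAlignment
NULL

.strongRatio <- function(lengths, threshold) {
  if (length(threshold) != 1L || !is.finite(threshold) ||
      threshold < 0 || threshold > 1)
    stop("'threshold' must lie in [0, 1]", call. = FALSE)
  mean(lengths > threshold)
}

#' @describeIn strongAlignmentRatio Ratio for one z-slice.
#' @param x A [VectorField-class] or [StackField-class].
#' @param threshold Alignment threshold (default 0.7).
#' @export
setMethod("strongAlignmentRatio", "VectorField",
          function(x, threshold = 0.7)
  .strongRatio(.validLengths(x), threshold))

#' @describeIn strongAlignmentRatio Ratio over valid cells pooled across z
#'   with equal weight.
#' @export
setMethod("strongAlignmentRatio", "StackField",
          function(x, threshold = 0.7)
  .strongRatio(.validLengths(x), threshold))

#' Strong-alignment ratio
#'
#' The volume ratio of strong alignment: the fraction of valid cells
#' (pooled over all z-slices) whose alignment length strictly exceeds the
#' threshold (default 0.7). Non-increasing in the threshold; 0 at
#' threshold 1.
#'
#' @return A number in \eqn{[0, 1]}.
#' @name strongAlignmentRatio
NULL

#' @describeIn filterHighAlignment High-alignment cells of one slice.
#' @param x A [VectorField-class] or [StackField-class].
#' @param threshold Visualization threshold (default 0.8).
#' @param zSpacing Slice spacing in micrometers; defaults to the value
#'   stored on the field(s).
#' @export
setMethod("filterHighAlignment", "VectorField",
          function(x, threshold = 0.8, zSpacing = NULL)
  .filterHigh(cbind(x@cells, z_index = x@zIndex), threshold,
              if (is.null(zSpacing)) x@zSpacing else zSpacing))

#' @describeIn filterHighAlignment High-alignment cells across the stack.
#' @export
setMethod("filterHighAlignment", "StackField",
          function(x, threshold = 0.8, zSpacing = NULL)
  .filterHigh(cells(x), threshold,
              if (is.null(zSpacing)) x@fields[[1L]]@zSpacing else zSpacing))

.filterHigh <- function(cellTable, threshold, zSpacing) {
  if (threshold < 0 || threshold > 1)
    stop("'threshold' must lie in [0, 1]", call. = FALSE)
  keep <- cellTable$status == "valid" & !is.na(cellTable$length) &
    cellTable$length > threshold
  out <- cellTable[keep, c("x", "y", "z_index", "length", "angle",
                           "n_segments"), drop = FALSE]
  out$z_um <- out$z_index * zSpacing
  rownames(out) <- NULL
  out
}

#' High-alignment cells for 3D visualization
#'
#' Valid cells whose alignment length strictly exceeds a threshold
#' (default 0.8), with the physical z coordinate
#' \code{z_um = z_index * zSpacing} attached — the subset rendered in 3D
#' stack views.
#'
#' @return A \code{data.frame} with columns \code{x}, \code{y},
#'   \code{z_index}, \code{length}, \code{angle}, \code{n_segments},
#'   \code{z_um}.
#' @name filterHighAlignment
NULL

#' Sweep the sampling-circle radius
#'
#' Recomputes the field at several sampling-circle radii and tabulates,
#' per radius: the mean alignment over valid cells, the mean quantized
#' segment count per circle, and the valid-cell fraction. The segment
#' count is averaged over \emph{all} grid positions (not only valid ones)
#' so that it grows monotonically with the radius — counts at a fixed
#' position can only grow as the circle does. Used to choose the working
#' radius: small circles see too few segments for a well-defined vector,
#' large ones average away local structure toward the global vector.
#'
#' @param segments A segment table.
#' @param grid A [GridSpec-class] template; its \code{circleRadius} is
#'   replaced by each sweep radius in turn.
#' @param radii Positive sampling-circle radii in pixels.
#' @param boundary A [CircularBoundary-class] or \code{NULL}.
#' @return A \code{data.frame} with columns \code{radius},
#'   \code{mean_alignment} (\code{NA} when no cell is valid),
#'   \code{mean_segment_count}, \code{valid_fraction} and
#'   \code{interior_above_min} (fraction of interior cells whose count
#'   strictly exceeds \code{grid@minFiberCount}).
#' @seealso [selectCircleRadius()]
#' @export
circleSizeSweep <- function(segments, grid, radii, boundary = NULL) {
  if (length(radii) == 0L || any(!is.finite(radii) | radii <= 0))
    stop("'radii' must be a non-empty vector of positive radii",
         call. = FALSE)
  rows <- lapply(radii, function(R) {
    g <- grid
    g@circleRadius <- as.numeric(R)
    fld <- computeField(segments, g, boundary)
    cl <- fld@cells
    interior <- cl$status %in% c("valid", "excluded_min_fibers")
    data.frame(
      radius = R,
      mean_alignment = if (any(cl$status == "valid"))
        mean(cl$length[cl$status == "valid"]) else NA_real_,
      mean_segment_count = mean(cl$n_segments),
      valid_fraction = mean(cl$status == "valid"),
      interior_above_min = if (any(interior))
        mean(cl$n_segments[interior] > grid@minFiberCount) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Heuristic choice of the sampling-circle radius
#'
#' Picks the smallest swept radius whose sampling circles contain enough
#' segments almost everywhere: the fraction of interior cells (cells not
#' excluded by the image or tumor boundary) with segment count strictly
#' above \code{minFiberCount} must reach \code{coverage} (default 90%).
#' This is a pragmatic selection rule for the radius sweep; the preferred
#' radius ultimately depends on image resolution and extraction quality.
#'
#' @param sweep Output of [circleSizeSweep()].
#' @param coverage Required interior coverage fraction (default 0.9).
#' @return The selected radius, or \code{NA} if no swept radius qualifies.
#' @export
selectCircleRadius <- function(sweep, coverage = 0.9) {
  ok <- which(!is.na(sweep$interior_above_min) &
                sweep$interior_above_min >= coverage)
  if (length(ok) == 0L) return(NA_real_)
  min(sweep$radius[ok])
}
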