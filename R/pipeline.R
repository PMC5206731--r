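## End-to-end analysis: fiber table -> quantized segments -> per-slice
## alignment fields -> pooled z-stack statistics.

#' Run the full alignment analysis
#'
#' Quantizes all fibers, computes the local alignment vector field of
#' every z-slice, pools the slices into a stack, and derives the summary
#' statistics: the normalized alignment distribution, the mean local
#' alignment and the strong-alignment ratio. Optionally sweeps the
#' sampling-circle radius. Deterministic given its inputs; with
#' \code{verbose = TRUE} it reports per-slice excluded-cell counts by
#' reason so the bookkeeping of the (typically ~10^4 per slice) vectors
#' can be audited.
#'
#' @param fibers A fiber table (see [readFiberTable()]); must be
#'   non-empty.
#' @param imageWidth,imageHeight Image size in pixels.
#' @param boundaries Per-slice circular boundaries as a \code{data.frame}
#'   with columns \code{z_index}, \code{cx}, \code{cy}, \code{r}, or
#'   \code{NULL} for none. Every fiber slice must have a boundary row when
#'   boundaries are given.
#' @param config An [AnalysisConfig-class].
#' @param sweepRadii Optional radii for a [circleSizeSweep()] on the first
#'   slice.
#' @param verbose Log progress and exclusion counts via [message()].
#' @return A list with components \code{stack} ([StackField-class]),
#'   \code{distribution}, \code{meanAlignment}, \code{strongRatio},
#'   \code{excluded} (per-slice status counts), \code{sweep} (or
#'   \code{NULL}) and \code{config}.
#' @examples
#' ft <- simulateRadial(radialSimConfig(seed = 1))
#' res <- runPipeline(ft, 512, 512,
#'                    boundaries = data.frame(z_index = 1, cx = 0, cy = 0,
#'                                            r = 150),
#'                    config = analysisConfig(), verbose = FALSE)
#' @export
runPipeline <- function(fibers, imageWidth, imageHeight, boundaries = NULL,
                        config = analysisConfig(), sweepRadii = NULL,
                        verbose = TRUE) {
  stopifnot(is(config, "AnalysisConfig"))
  checkFiberTable(fibers, allowEmpty = FALSE)
  zs <- sort(unique(fibers$z_index))
  if (!is.null(boundaries)) {
    missing <- setdiff(zs, boundaries$z_index)
    if (length(missing))
      stop("no boundary given for z-slice(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  grid <- gridSpec(imageWidth, imageHeight, spacing = config@spacing,
                   circleRadius = config@circleRadius,
                   minFiberCount = config@minFiberCount)
  if (verbose) {
    message(sprintf(
      "pipeline: %d z-slice(s), grid %d x %d px spacing %g, R = %g px, F > %d, L = %g px",
      length(zs), imageWidth, imageHeight, config@spacing,
      config@circleRadius, config@minFiberCount, config@filterLength))
  }
  segments <- quantizeFibers(fibers, config@filterLength)
  excluded <- NULL
  fields <- lapply(zs, function(z) {
    segz <- segments[segments$z_index == z, , drop = FALSE]
    if (nrow(segz) == 0L)
      stop("z-slice ", z, " has no quantized segments ",
           "(all fibers shorter than the filtering length?)",
           call. = FALSE)
    bnd <- NULL
    if (!is.null(boundaries)) {
      row <- boundaries[boundaries$z_index == z, , drop = FALSE]
      bnd <- circularBoundary(c(row$cx[1L], row$cy[1L]), row$r[1L])
    }
    fld <- computeField(segz, grid, bnd, zIndex = z,
                        zSpacing = config@zSpacing,
                        pixelSize = config@pixelSize)
    tab <- table(factor(fld@cells$status, levels = .CELL_STATUSES))
    excluded <<- rbind(excluded,
                       data.frame(z_index = z, as.list(tab),
                                  check.names = FALSE))
    if (verbose)
      message(sprintf(
        "  z = %d: %d segments; %d valid, %d image-boundary, %d tumor-boundary, %d below min count",
        z, nrow(segz), tab[["valid"]], tab[["excluded_image_boundary"]],
        tab[["excluded_tumor_boundary"]], tab[["excluded_min_fibers"]]))
    fld
  })
  stack <- stackField(fields)
  sweep <- NULL
  if (!is.null(sweepRadii)) {
    seg1 <- segments[segments$z_index == zs[1L], , drop = FALSE]
    bnd1 <- NULL
    if (!is.null(boundaries)) {
      row <- boundaries[boundaries$z_index == zs[1L], , drop = FALSE]
      bnd1 <- circularBoundary(c(row$cx[1L], row$cy[1L]), row$r[1L])
    }
    sweep <- circleSizeSweep(seg1, grid, sweepRadii, bnd1)
  }
  nvalid <- sum(excluded$valid)
  if (nvalid == 0L)
    stop("no valid cells in any z-slice; relax the exclusion parameters",
         call. = FALSE)
  res <- list(stack = stack,
              distribution = alignmentDistribution(stack, config@binWidth),
              meanAlignment = meanAlignment(stack),
              strongRatio = strongAlignmentRatio(stack,
                                                 config@strongThreshold),
              excluded = excluded, sweep = sweep, config = config)
  if (verbose)
    message(sprintf(
      "  pooled: %d valid cells; mean alignment %.4f; strong ratio (> %g) %.4f",
      nvalid, res$meanAlignment, config@strongThreshold, res$strongRatio))
  res
}
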