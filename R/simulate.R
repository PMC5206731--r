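## In-silico fiber generators used to validate the alignment statistics.
##
## Two reference configurations: (1) a homogeneous box of identical
## straight fibers at a common base orientation with Gaussian angular
## noise, whose expected alignment length follows the wrapped-normal
## closed form exp(-2 sigma^2); (2) a heterogeneous field of fibers
## radiating from a quarter-disk boundary anchored at the box corner,
## where the global alignment vector under-reports order (~0.64, pointing
## along the 45-degree bisector) while local sampling circles recover it.
## Both are bit-reproducible from their seed.

## Run fn with a private RNG stream seeded by `seed`, restoring the
## caller's RNG state afterwards.
.withSeed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Simulate a homogeneous perturbed fiber field
#'
#' Generates \code{nFibers} straight two-vertex fibers in a square box.
#' Each fiber's axial angle is \code{baseAngle} plus Gaussian noise with
#' standard deviation \code{noiseStd} degrees, wrapped into
#' \eqn{[0, 180)}; midpoints are uniform in the box, redrawn until both
#' endpoints lie inside it. Identical configurations (including the seed)
#' give bit-identical fiber tables.
#'
#' @param config A [UniformSimConfig-class].
#' @return A fiber table (see [checkFiberTable()]) with one z-slice.
#' @examples
#' ft <- simulateUniform(uniformSimConfig(noiseStd = 20, seed = 7))
#' @export
simulateUniform <- function(config) {
  stopifnot(is(config, "UniformSimConfig"))
  validObject(config)
  B <- config@boxSize
  half <- config@fiberLength / 2
  .withSeed(config@seed, function() {
    n <- config@nFibers
    x1 <- y1 <- x2 <- y2 <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        ang <- .mod180(config@baseAngle + stats::rnorm(1, 0, config@noiseStd))
        mx <- stats::runif(1, 0, B)
        my <- stats::runif(1, 0, B)
        dx <- half * cos(ang * .DEG2RAD)
        dy <- half * sin(ang * .DEG2RAD)
        if (mx - abs(dx) >= 0 && mx + abs(dx) <= B &&
            my - abs(dy) >= 0 && my + abs(dy) <= B) {
          x1[i] <- mx - dx; y1[i] <- my - dy
          x2[i] <- mx + dx; y2[i] <- my + dy
          break
        }
      }
    }
    straightFiberTable(x1, y1, x2, y2)
  })
}

#' Simulate radially aligned fibers around a circular boundary
#'
#' Generates straight fibers radiating from a quarter-disk (tumor)
#' boundary anchored at the box origin corner. Midpoints are drawn
#' uniformly from the quarter annulus between the boundary radius and
#' \code{outerRadius} (the global sampling circle; default the box size),
#' by rejection; a draw is accepted only when both endpoints lie inside
#' the box and outside the tumor disk. Each fiber's axial angle is the
#' radial direction from the boundary center to its midpoint plus
#' Gaussian noise, wrapped into \eqn{[0, 180)}.
#'
#' @param config A [RadialSimConfig-class].
#' @return A fiber table with one z-slice.
#' @examples
#' ft <- simulateRadial(radialSimConfig(seed = 3))
#' @export
simulateRadial <- function(config) {
  stopifnot(is(config, "RadialSimConfig"))
  validObject(config)
  B <- config@boxSize
  half <- config@fiberLength / 2
  rt <- config@boundary@radius
  rout <- config@outerRadius
  .withSeed(config@seed, function() {
    n <- config@nFibers
    x1 <- y1 <- x2 <- y2 <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        mx <- stats::runif(1, 0, B)
        my <- stats::runif(1, 0, B)
        d <- sqrt(mx^2 + my^2)
        if (d <= rt || d > rout) next
        radial <- .mod180(atan2(my, mx) / .DEG2RAD)
        ang <- .mod180(radial + stats::rnorm(1, 0, config@noiseStd))
        dx <- half * cos(ang * .DEG2RAD)
        dy <- half * sin(ang * .DEG2RAD)
        e1 <- c(mx - dx, my - dy); e2 <- c(mx + dx, my + dy)
        if (any(c(e1, e2) < 0) || any(c(e1, e2) > B)) next
        if (sqrt(sum(e1^2)) <= rt || sqrt(sum(e2^2)) <= rt) next
        x1[i] <- e1[1]; y1[i] <- e1[2]; x2[i] <- e2[1]; y2[i] <- e2[2]
        break
      }
    }
    straightFiberTable(x1, y1, x2, y2)
  })
}

#' Reference local sampling circles for the radial configuration
#'
#' Centers of the eight local sampling circles used to probe the radial
#' configuration: four azimuths (11.25, 33.75, 56.25, 78.75 degrees) on
#' each of two arcs concentric with the tumor boundary, at distances
#' \code{boundary radius + c(60, 160)} from its center.
#'
#' @param boundary The tumor [CircularBoundary-class].
#' @param offsets Radial offsets of the two arcs, pixels.
#' @param azimuths Azimuths of the circle centers, degrees.
#' @return A two-column matrix of \code{(x, y)} centers.
#' @export
localCirclePositions <- function(boundary, offsets = c(60, 160),
                                 azimuths = c(11.25, 33.75, 56.25, 78.75)) {
  d <- boundary@radius + offsets
  az <- azimuths * .DEG2RAD
  cx <- boundary@center[1] + outer(d, az, function(r, a) r * cos(a))
  cy <- boundary@center[2] + outer(d, az, function(r, a) r * sin(a))
  cbind(x = as.numeric(t(cx)), y = as.numeric(t(cy)))
}

## Built-in replica statistics. Each takes the fiber table and returns a
## scalar: the fibers' own axial angles are used directly (straight
## two-vertex fibers), matching the construction of the reference
## configurations.
.fiberAngles <- function(fibers) {
  i1 <- fibers$vertex_index == 1L
  i2 <- fibers$vertex_index == 2L
  segmentAngle(cbind(fibers$x[i1], fibers$y[i1]),
               cbind(fibers$x[i2], fibers$y[i2]))
}

.REPLICA_STATS <- list(
  alignment_length = function(fibers)
    alignmentVector(.fiberAngles(fibers))@length,
  alignment_angle = function(fibers)
    alignmentVector(.fiberAngles(fibers))@angle
)

#' Replicated simulation statistics
#'
#' Runs a simulator configuration \code{nReplicas} times (replica \code{i}
#' uses seed \code{config seed + i}) and summarizes a scalar statistic
#' across replicas. Built-in statistics: \code{"alignment_length"} (the
#' alignment vector length over all fiber angles) and
#' \code{"alignment_angle"} (its axial angle); a custom
#' \code{function(fibers)} is also accepted. Angle statistics are averaged
#' the axial-circular way (double, average, halve), since arithmetic means
#' fail near the 0/180 wrap; their spread is the standard deviation of the
#' wrapped deviations from that mean.
#'
#' @param config A [UniformSimConfig-class] or [RadialSimConfig-class].
#' @param nReplicas Number of replicas (\eqn{\ge 1}).
#' @param statistic Name of a built-in statistic or a function.
#' @return A list with \code{values} (per replica), \code{mean} and
#'   \code{sd}.
#' @examples
#' replicateSim(uniformSimConfig(noiseStd = 20), 5, "alignment_length")
#' @export
replicateSim <- function(config, nReplicas, statistic = "alignment_length") {
  if (nReplicas < 1L) stop("'nReplicas' must be >= 1", call. = FALSE)
  angular <- FALSE
  if (is.character(statistic)) {
    if (!statistic %in% names(.REPLICA_STATS))
      stop("unknown statistic '", statistic, "'; available: ",
           paste(names(.REPLICA_STATS), collapse = ", "), call. = FALSE)
    angular <- statistic == "alignment_angle"
    statistic <- .REPLICA_STATS[[statistic]]
  }
  simulate <- if (is(config, "UniformSimConfig")) simulateUniform
              else if (is(config, "RadialSimConfig")) simulateRadial
              else stop("unsupported simulator config", call. = FALSE)
  values <- vapply(seq_len(nReplicas), function(i) {
    cfg <- config
    cfg@seed <- config@seed + as.integer(i)
    statistic(simulate(cfg))
  }, numeric(1))
  if (angular) {
    m <- axialMean(values)
    dev <- ((values - m + 90) %% 180) - 90
    list(values = values, mean = m,
         sd = if (nReplicas > 1L) stats::sd(dev) else 0)
  } else {
    list(values = values, mean = mean(values),
         sd = if (nReplicas > 1L) stats::sd(values) else 0)
  }
}
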