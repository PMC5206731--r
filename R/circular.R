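## Axial-angle circular statistics.
##
## Fiber orientations are axial data: a fiber has no head or tail, so its
## angle lives in [0, 180) degrees. The standard trick is to double the
## angles onto the full circle, do ordinary circular statistics there, and
## halve the resulting direction back. All interfaces use degrees.

.DEG2RAD <- pi / 180

## MRV lengths below this are treated as exactly zero (direction undefined);
## covers floating-point cancellation for symmetric inputs.
.ZERO_TOL <- 1e-9

.mod180 <- function(a) a %% 180
.mod360 <- function(a) a %% 360

.checkAngles <- function(angles, what = "angles") {
  if (length(angles) == 0L)
    stop(sprintf("'%s' must contain at least one angle", what), call. = FALSE)
  if (!is.numeric(angles) || !all(is.finite(angles)))
    stop(sprintf("'%s' must be finite numeric angles", what), call. = FALSE)
  invisible(angles)
}

#' Map an axial angle onto the full circle
#'
#' Doubles an axial fiber angle \eqn{\alpha \in [0, 180)} degrees onto the
#' circle, \eqn{\theta = 2\alpha \in [0, 360)}. This is the first step of
#' the alignment-vector construction: it identifies the two directions of an
#' undirected fiber so that ordinary circular statistics apply.
#'
#' @param alpha Axial angle(s) in degrees, each in \eqn{[0, 180)}.
#' @return Circular angle(s) \eqn{2\alpha} in degrees.
#' @examples
#' axialToCircular(c(0, 90, 135))
#' @export
axialToCircular <- function(alpha) {
  .checkAngles(alpha, "alpha")
  if (any(alpha < 0 | alpha >= 180))
    stop("axial angles must lie in [0, 180) degrees", call. = FALSE)
  2 * alpha
}

#' Mean resultant vector of circular angles
#'
#' Computes the mean resultant vector (MRV) of a set of circular angles:
#' the vector sum of the unit vectors \eqn{(\cos\theta_i, \sin\theta_i)}
#' divided by the number of angles \eqn{N}. The MRV length measures angular
#' concentration (1 = all identical, 0 = perfect cancellation); the MRV
#' angle is undefined (\code{NA}) when the length is numerically zero
#' (below \code{1e-9}).
#'
#' @param thetas Circular angles in degrees; reduced modulo 360.
#' @return A list with components \code{length} (in \eqn{[0, 1]}) and
#'   \code{angle} (degrees in \eqn{[0, 360)}, \code{NA} when
#'   \code{length == 0}).
#' @examples
#' meanResultantVector(c(0, 90))   # length 1/sqrt(2), angle 45
#' meanResultantVector(c(0, 180))  # length 0, angle NA
#' @export
meanResultantVector <- function(thetas) {
  .checkAngles(thetas, "thetas")
  th <- .mod360(thetas) * .DEG2RAD
  cbar <- mean(cos(th))
  sbar <- mean(sin(th))
  len <- sqrt(cbar^2 + sbar^2)
  if (len < .ZERO_TOL)
    return(list(length = 0, angle = NA_real_))
  len <- min(len, 1)
  list(length = len, angle = .mod360(atan2(sbar, cbar) / .DEG2RAD))
}

#' Alignment vector of axial fiber angles
#'
#' The central statistic of the method. Each axial angle is doubled onto
#' the circle, the mean resultant vector of the doubled angles is computed,
#' and its angle is halved back to the axial range \eqn{[0, 180)}. The
#' resulting length is 1 for perfectly aligned fibers and 0 when the
#' orientations cancel (e.g. equal numbers at 45 and 135 degrees); it
#' equals the 2D nematic orientational order parameter of the same angles
#' (see [orientationalOrderParameter()]). Angles are unweighted: length
#' weighting is achieved upstream by quantizing fibers into equal-length
#' segments.
#'
#' @param angles Axial angles in degrees; reduced modulo 180 before
#'   doubling.
#' @param position Optional grid position \code{(x, y)} in pixels.
#' @return An [AlignmentVector-class].
#' @examples
#' alignmentVector(rep(90, 10))     # length 1, axial angle 90
#' alignmentVector(c(45, 135))      # length 0, angle undefined
#' @export
alignmentVector <- function(angles, position = numeric(0)) {
  .checkAngles(angles)
  mrv <- meanResultantVector(axialToCircular(.mod180(angles)))
  new("AlignmentVector", length = mrv$length,
      angle = if (is.na(mrv$angle)) NA_real_ else .mod180(mrv$angle / 2),
      nSegments = length(angles), position = as.numeric(position))
}

#' Nematic orientational order parameter
#'
#' Computes the 2D orientational order parameter \eqn{\mu}: the maximal
#' eigenvalue of the 2 x 2 symmetric order tensor
#' \deqn{A = \begin{pmatrix} \langle\cos 2\alpha\rangle & \langle\sin 2\alpha\rangle \\
#'   \langle\sin 2\alpha\rangle & -\langle\cos 2\alpha\rangle \end{pmatrix}}
#' built from the means of \eqn{\cos 2\alpha_i} and \eqn{\sin 2\alpha_i}
#' over the fiber angles. It equals the alignment vector length of the same
#' angle set; the package computes it by explicit eigendecomposition
#' (\code{\link[base]{eigen}}), not through that equivalence, so that it can
#' serve as an independent cross-check of [alignmentVector()].
#'
#' @param angles Axial angles in degrees; reduced modulo 180.
#' @return The order parameter \eqn{\mu \in [0, 1]}.
#' @examples
#' orientationalOrderParameter(rep(30, 5))  # 1
#' orientationalOrderParameter(c(45, 135))  # 0
#' @export
orientationalOrderParameter <- function(angles) {
  .checkAngles(angles)
  a2 <- 2 * .mod180(angles) * .DEG2RAD
  c2 <- mean(cos(a2))
  s2 <- mean(sin(a2))
  A <- matrix(c(c2, s2, s2, -c2), nrow = 2)
  max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
}

#' Axial circular mean of angles
#'
#' Averages axial angles (degrees in \eqn{[0, 180)}) the circular way:
#' double, average the unit vectors, halve the mean direction. Used to
#' average alignment-vector angles across simulation replicas, where a naive
#' arithmetic mean fails near the 0/180 wrap.
#'
#' @param angles Axial angles in degrees.
#' @return The axial mean in \eqn{[0, 180)} degrees, or \code{NA} if the
#'   doubled angles cancel.
#' @examples
#' axialMean(c(179, 1))  # 0, not 90
#' @export
axialMean <- function(angles) {
  .checkAngles(angles)
  mrv <- meanResultantVector(axialToCircular(.mod180(angles)))
  if (is.na(mrv$angle)) NA_real_ else .mod180(mrv$angle / 2)
}

#' Expected alignment length under Gaussian angular noise
#'
#' Closed-form expectation for the wrapped-normal validation model: fibers
#' at a common base angle perturbed by Gaussian noise with standard
#' deviation \eqn{\sigma}. The doubled angles follow a wrapped normal with
#' mean resultant \eqn{\rho = \exp(-2\sigma^2)} (\eqn{\sigma} in radians),
#' so the population alignment length is \eqn{\exp(-2\sigma^2)}. For a
#' finite sample of \eqn{n} fibers the sample alignment length is biased
#' upward; the exact second moment is
#' \eqn{E[\bar R^2] = (1 + (n - 1)\rho^2)/n}, and with finite \code{n} this
#' function returns its square root (the root-mean-square alignment
#' length), the quantity against which simulation means of \eqn{\bar R^2}
#' can be tested without bias.
#'
#' @param sigmaDeg Noise standard deviation in degrees.
#' @param n Number of fibers per sample; \code{Inf} (default) gives the
#'   population value \eqn{\exp(-2\sigma^2)}.
#' @return Expected alignment length(s).
#' @examples
#' expectedAlignment(20)        # exp(-2 * (20 * pi/180)^2)
#' expectedAlignment(60, n = 100)
#' @export
expectedAlignment <- function(sigmaDeg, n = Inf) {
  if (any(sigmaDeg < 0)) stop("'sigmaDeg' must be >= 0", call. = FALSE)
  rho <- exp(-2 * (sigmaDeg * .DEG2RAD)^2)
  if (is.infinite(n)) return(rho)
  sqrt((1 + (n - 1) * rho^2) / n)
}

#' @describeIn alignmentLength Length of an alignment vector.
#' @param x An object carrying alignment values.
#' @export
setMethod("alignmentLength", "AlignmentVector", function(x) x@length)

#' @describeIn axialAngle Axial angle (degrees) of an alignment vector;
#'   \code{NA} when the length is zero.
#' @param x An object carrying an axial direction.
#' @export
setMethod("axialAngle", "AlignmentVector", function(x) x@angle)

#' @describeIn nSegments Number of quantized segments behind an alignment
#'   vector.
#' @param x An object carrying a segment count.
#' @export
setMethod("nSegments", "AlignmentVector", function(x) x@nSegments)

#' Accessors for alignment objects
#'
#' \code{alignmentLength}, \code{axialAngle} and \code{nSegments} extract
#' the length in \eqn{[0, 1]}, the axial angle in degrees and the
#' contributing segment count from an [AlignmentVector-class].
#'
#' @name alignmentLength
NULL

#' @name axialAngle
#' @rdname alignmentLength
NULL

#' @name nSegments
#' @rdname alignmentLength
NULL
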