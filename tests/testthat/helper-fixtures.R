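# Shared fixtures, all generated in code.

# Random axial angle sets of varying size, under a fixed seed.
randomAngleSets <- function(n, sizes = 1:200, seed = 42) {
  withr::with_seed(seed, lapply(seq_len(n), function(i)
    stats::runif(sample(sizes, 1L), 0, 180)))
}

# Rotate points (two-column matrix) by phi degrees about the origin.
rotatePoints <- function(p, phiDeg) {
  phi <- phiDeg * pi / 180
  cbind(p[, 1] * cos(phi) - p[, 2] * sin(phi),
        p[, 1] * sin(phi) + p[, 2] * cos(phi))
}

# A jagged polyline with a given total arclength, made of random-direction
# edges; used for quantization properties on curved paths.
jaggedPolyline <- function(totalLength, nEdges = 6L, seed = 1) {
  withr::with_seed(seed, {
    steps <- stats::runif(nEdges)
    steps <- steps / sum(steps) * totalLength
    dirs <- cumsum(stats::runif(nEdges, -40, 40)) * pi / 180
    dx <- steps * cos(dirs)
    dy <- steps * sin(dirs)
    cbind(c(0, cumsum(dx)), c(0, cumsum(dy)))
  })
}

# A dense homogeneous field of parallel segments on a lattice: one
# unit-weight quantized segment per lattice point, all at `angle`.
latticeSegments <- function(width, height, step = 2, angle = 30) {
  xs <- seq(1, width, by = step)
  ys <- seq(1, height, by = step)
  xm <- rep(xs, times = length(ys))
  ym <- rep(ys, each = length(xs))
  a <- angle * pi / 180
  data.frame(fiber_id = seq_along(xm), z_index = 1L, seg_index = 1L,
             x1 = xm - cos(a), y1 = ym - sin(a),
             x2 = xm + cos(a), y2 = ym + sin(a),
             xm = xm, ym = ym, angle = angle)
}

# A VectorField whose valid cells carry prescribed alignment lengths
# (remaining cells are excluded); for statistics tests.
fieldWithLengths <- function(lengths, angle = 90) {
  k <- length(lengths)
  side <- (ceiling(sqrt(k)) + 1) * 5  # grid with >= k cells at spacing 5
  pos <- buildGrid(side, side, 5)
  n <- nrow(pos)
  stopifnot(n >= k)
  status <- c(rep("valid", k), rep("excluded_min_fibers", n - k))
  len <- c(lengths, rep(NA_real_, n - k))
  ang <- ifelse(is.na(len) | len == 0, NA_real_, angle)
  cells <- data.frame(x = pos[, 1], y = pos[, 2], status = status,
                      length = len, angle = ang,
                      n_segments = ifelse(status == "valid", 20L, 0L))
  new("VectorField", grid = gridSpec(side, side, minFiberCount = 10L),
      cells = cells, boundary = NULL, zIndex = 1L, zSpacing = 1,
      pixelSize = 0.83)
}

stackWithLengths <- function(lengths, angle = 90) {
  stackField(fieldWithLengths(lengths, angle))
}
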