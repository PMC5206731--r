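test_that("segment angle is axial and direction-free", {
  expect_equal(segmentAngle(c(0, 0), c(1, 1)), 45)
  expect_equal(segmentAngle(c(0, 0), c(-1, 1)), 135)
  expect_equal(segmentAngle(c(1, 1), c(0, 0)), 45)  # reversed endpoints
  expect_equal(segmentAngle(c(0, 0), c(0, 5)), 90)  # vertical
  expect_equal(segmentAngle(c(0, 0), c(-3, 0)), 0)  # horizontal, flipped
  expect_error(segmentAngle(c(1, 2), c(1, 2)), "degenerate")
})

test_that("straight fibers quantize into floor(length/L) equal segments", {
  v <- cbind(c(0, 40), c(0, 0))
  seg <- quantizeFiber(v, 5)
  expect_identical(nrow(seg), 8L)
  expect_equal(seg$angle, rep(0, 8))
  expect_equal(sqrt((seg$x2 - seg$x1)^2 + (seg$y2 - seg$y1)^2), rep(5, 8))
  expect_equal(seg$xm, seq(2.5, 37.5, by = 5))

  # remainder 2 dropped
  expect_identical(nrow(quantizeFiber(cbind(c(0, 12), c(0, 0)), 5)), 2L)
  # below the filtering length: noise, dropped entirely
  expect_identical(nrow(quantizeFiber(cbind(c(0, 3), c(0, 0)), 5)), 0L)

  expect_error(quantizeFiber(v, 0), "positive")
  expect_error(quantizeFiber(v[1, , drop = FALSE]), "n >= 2")
})

test_that("oblique straight fibers keep their angle on every segment", {
  for (ang in c(10, 45, 90, 137.5)) {
    a <- ang * pi / 180
    v <- rbind(c(3, 7), c(3 + 23 * cos(a), 7 + 23 * sin(a)))
    seg <- quantizeFiber(v, 5)
    expect_identical(nrow(seg), 4L)
    expect_equal(seg$angle, rep(ang, 4), tolerance = 1e-9)
  }
})

test_that("curved paths: arclength step is exact, chord is at most L", {
  v <- jaggedPolyline(37, nEdges = 7, seed = 3)
  L <- 5
  seg <- quantizeFiber(v, L)
  expect_identical(nrow(seg), as.integer(floor(37 / L)))
  chord <- sqrt((seg$x2 - seg$x1)^2 + (seg$y2 - seg$y1)^2)
  expect_true(all(chord <= L + 1e-9))
  expect_equal(seg$xm, (seg$x1 + seg$x2) / 2)
  expect_equal(seg$ym, (seg$y1 + seg$y2) / 2)
  # midpoints never leave the vertex bounding box by more than L
  expect_true(all(seg$xm >= min(v[, 1]) - L & seg$xm <= max(v[, 1]) + L))
  expect_true(all(seg$ym >= min(v[, 2]) - L & seg$ym <= max(v[, 2]) + L))
})

test_that("total segment count is sum of floor(arclength/L) over fibers", {
  lens <- c(3, 12, 40, 27.5, 4.9, 55)
  tabs <- lapply(seq_along(lens), function(i) {
    v <- jaggedPolyline(lens[i], nEdges = 5, seed = i)
    data.frame(fiber_id = i, z_index = 1L,
               vertex_index = seq_len(nrow(v)), x = v[, 1], y = v[, 2])
  })
  fibers <- do.call(rbind, tabs)
  seg <- quantizeFibers(fibers, 5)
  arclens <- vapply(tabs, function(t) fiberArclength(cbind(t$x, t$y)),
                    numeric(1))
  nseg <- floor(arclens / 5 + 1e-9)  # same exact-multiple guard as the code
  expect_identical(nrow(seg), as.integer(sum(nseg)))
  # stable order: fiber id, then position along the fiber
  expect_identical(seg$fiber_id, rep(seq_along(lens), nseg))
  expect_true(all(unlist(tapply(seg$seg_index, seg$fiber_id, diff)) == 1))
})

test_that("quantization commutes with rigid motions", {
  v <- jaggedPolyline(42, nEdges = 6, seed = 9)
  seg <- quantizeFiber(v, 5)
  phi <- 28
  shift <- c(13.7, -4.2)
  vr <- sweep(rotatePoints(v, phi), 2, shift, `+`)
  segr <- quantizeFiber(vr, 5)
  expect_identical(nrow(segr), nrow(seg))
  mid <- sweep(rotatePoints(cbind(seg$xm, seg$ym), phi), 2, shift, `+`)
  expect_equal(segr$xm, mid[, 1], tolerance = 1e-9)
  expect_equal(segr$ym, mid[, 2], tolerance = 1e-9)
  expect_equal(segr$angle, (seg$angle + phi) %% 180, tolerance = 1e-9)
})

test_that("quantizeFibers handles empty and mixed input", {
  empty <- data.frame(fiber_id = character(0), z_index = integer(0),
                      vertex_index = integer(0), x = numeric(0),
                      y = numeric(0))
  expect_identical(nrow(quantizeFibers(empty)), 0L)

  hundred <- straightFiberTable(rep(0, 100), seq(0, 99), rep(40, 100),
                                seq(0, 99))
  expect_identical(nrow(quantizeFibers(hundred, 5)), 800L)

  mix <- rbind(straightFiberTable(0, 0, 3, 0, fiberId = 1),
               straightFiberTable(0, 10, 40, 10, fiberId = 2))
  expect_identical(nrow(quantizeFibers(mix, 5)), 8L)
})

test_that("fiber tables are validated", {
  bad <- data.frame(fiber_id = 1, z_index = 1L, vertex_index = 1L,
                    x = 0, y = 0)
  expect_error(checkFiberTable(bad), "fewer than 2 vertices")
  expect_error(checkFiberTable(data.frame(x = 1)), "missing column")
  nonfin <- straightFiberTable(0, 0, 1, 1)
  nonfin$x[2] <- NaN
  expect_error(checkFiberTable(nonfin), "non-finite")
})
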