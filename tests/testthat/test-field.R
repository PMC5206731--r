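test_that("grid bookkeeping matches the published cell counts", {
  g <- buildGrid(512, 512, 5)
  expect_identical(nrow(g), 10609L)           # 103 x 103
  expect_identical(length(unique(g[, "x"])), 103L)

  g <- buildGrid(10, 10, 5)                   # positions 1 and 6 per axis
  expect_equal(unname(g),
               cbind(c(1, 6, 1, 6), c(1, 1, 6, 6)))

  expect_identical(nrow(buildGrid(10, 10, 50)), 1L)
  expect_error(buildGrid(10, 10, 0), "positive")
})

test_that("grid counts match brute-force enumeration", {
  dims <- withr::with_seed(3, sample(1:200, 20, replace = TRUE))
  spacings <- withr::with_seed(4, sample(1:30, 20, replace = TRUE))
  for (i in seq_along(dims)) {
    d <- dims[i]; s <- spacings[i]
    brute <- sum(1 + (0:1000) * s <= d)
    expect_identical(nrow(buildGrid(d, 1, s)), as.integer(brute))
  }
})

test_that("cell classification applies exclusions in priority order", {
  grid <- gridSpec(512, 512, circleRadius = 25, minFiberCount = 10)
  tumor <- circularBoundary(c(256, 256), 100)

  # circle leaves the image
  expect_identical(classifyCell(c(2, 2), grid, NULL, 100L),
                   "excluded_image_boundary")
  # image boundary outranks the tumor check
  expect_identical(classifyCell(c(2, 2), grid, circularBoundary(c(2, 2), 50),
                                100L),
                   "excluded_image_boundary")
  # inside the tumor disk
  expect_identical(classifyCell(c(256, 256), grid, tumor, 100L),
                   "excluded_tumor_boundary")
  # circle intersecting the disk from outside (distance < r_tumor + R)
  expect_identical(classifyCell(c(256 + 120, 256), grid, tumor, 100L),
                   "excluded_tumor_boundary")
  # tangent circles (distance == r_tumor + R) are kept
  expect_identical(classifyCell(c(256 + 125, 256), grid, tumor, 100L),
                   "valid")
  # minimum count is strict: count must exceed F
  expect_identical(classifyCell(c(256, 30 + 226), grid, NULL, 5L),
                   "excluded_min_fibers")
  expect_identical(classifyCell(c(256, 256), grid, NULL, 10L),
                   "excluded_min_fibers")
  expect_identical(classifyCell(c(256, 256), grid, NULL, 11L), "valid")
})

test_that("segment gathering is midpoint-based and boundary-inclusive", {
  seg <- latticeSegments(20, 20, step = 1)
  # a midpoint at exactly the radius is included
  picked <- segmentsInCircle(seg, c(10, 10), 3)
  d <- sqrt((picked$xm - 10)^2 + (picked$ym - 10)^2)
  expect_true(any(abs(d - 3) < 1e-12))
  expect_true(all(d <= 3))
  # brute-force count
  expect_identical(nrow(picked),
                   sum((seg$xm - 10)^2 + (seg$ym - 10)^2 <= 9))
  # no segments in an empty region
  expect_identical(nrow(segmentsInCircle(seg, c(1000, 1000), 3)), 0L)
  # a huge circle gathers everything
  expect_identical(nrow(segmentsInCircle(seg, c(10, 10), 1e4)), nrow(seg))
})

test_that("homogeneous parallel field: every valid cell equals the global vector", {
  seg <- latticeSegments(60, 60, step = 2, angle = 30)
  fld <- computeField(seg, gridSpec(60, 60, spacing = 5, circleRadius = 10,
                                    minFiberCount = 10))
  v <- validCells(fld)
  expect_gt(nrow(v), 0)
  g <- globalAlignment(seg)
  expect_equal(v$length, rep(1, nrow(v)))
  expect_equal(v$angle, rep(30, nrow(v)), tolerance = 1e-9)
  expect_equal(alignmentLength(g), 1)
  expect_equal(axialAngle(g), 30)
  # interior cells away from the image edge are all valid
  interior <- fld@cells$status != "excluded_image_boundary"
  expect_true(all(fld@cells$status[interior] == "valid"))
})

test_that("empty segment set: interior cells fail the strict minimum-count rule", {
  fld <- computeField(.emptyseg <- quantizeFibers(
    straightFiberTable(numeric(0), numeric(0), numeric(0), numeric(0))),
    gridSpec(60, 60, spacing = 5, circleRadius = 10, minFiberCount = 0))
  st <- fld@cells$status
  expect_true(all(st %in% c("excluded_image_boundary",
                            "excluded_min_fibers")))
  expect_true(any(st == "excluded_min_fibers"))  # 0 <= 0 fails strict >
  expect_identical(sum(st == "valid"), 0L)
})

test_that("statuses are exhaustive and vectors present iff valid", {
  ft <- simulateRadial(radialSimConfig(nFibers = 200, seed = 5))
  seg <- quantizeFibers(ft, 5)
  fld <- computeField(seg, gridSpec(512, 512, spacing = 25,
                                    circleRadius = 25, minFiberCount = 10),
                      circularBoundary(c(0, 0), 150))
  cl <- cells(fld)
  expect_true(all(cl$status %in% c("valid", "excluded_image_boundary",
                                   "excluded_tumor_boundary",
                                   "excluded_min_fibers")))
  expect_true(all(is.na(cl$length[cl$status != "valid"])))
  expect_true(all(!is.na(cl$length[cl$status == "valid"])))
})

test_that("field computation is translation-equivariant", {
  ft <- simulateUniform(uniformSimConfig(boxSize = 80, nFibers = 30,
                                         fiberLength = 20, noiseStd = 40,
                                         seed = 8))
  seg <- quantizeFibers(ft, 5)
  grid <- gridSpec(120, 120, spacing = 5, circleRadius = 15,
                   minFiberCount = 3)
  fld <- computeField(seg, grid)

  shift <- 20  # integer multiple of the spacing
  seg2 <- seg
  for (col in c("x1", "x2", "xm")) seg2[[col]] <- seg2[[col]] + shift
  for (col in c("y1", "y2", "ym")) seg2[[col]] <- seg2[[col]] + shift
  grid2 <- gridSpec(120 + shift, 120 + shift, spacing = 5,
                    circleRadius = 15, minFiberCount = 3)
  fld2 <- computeField(seg2, grid2)

  c1 <- cells(fld)
  c2 <- cells(fld2)
  c2s <- c2[c2$x > shift & c2$y > shift, , drop = FALSE]
  m1 <- c1[match(paste(c2s$x - shift, c2s$y - shift),
                 paste(c1$x, c1$y)), , drop = FALSE]
  keep <- m1$status != "excluded_image_boundary" &
    c2s$status != "excluded_image_boundary"
  expect_gt(sum(keep & m1$status == "valid"), 0)
  expect_identical(c2s$status[keep], m1$status[keep])
  expect_equal(c2s$length[keep], m1$length[keep])
  expect_equal(c2s$angle[keep], m1$angle[keep])
})

test_that("global alignment of balanced perpendicular populations cancels", {
  seg <- rbind(latticeSegments(20, 20, step = 2, angle = 10),
               latticeSegments(20, 20, step = 2, angle = 100))
  expect_identical(alignmentLength(globalAlignment(seg)), 0)
  expect_error(globalAlignment(latticeSegments(4, 2)[0, ]), "zero segments")
})

test_that("radial configuration: local vectors point along the radial direction", {
  ft <- simulateRadial(radialSimConfig(seed = 13))
  seg <- quantizeFibers(ft, 5)
  centers <- localCirclePositions(circularBoundary(c(0, 0), 150))
  for (i in seq_len(nrow(centers))) {
    inC <- segmentsInCircle(seg, centers[i, ], 50)
    v <- alignmentVector(inC$angle)
    expect_gt(alignmentLength(v), 0.9)
    radial <- (atan2(centers[i, 2], centers[i, 1]) * 180 / pi) %% 180
    dev <- abs(axialAngle(v) - radial) %% 180
    expect_lt(min(dev, 180 - dev), 6)
  }
})
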