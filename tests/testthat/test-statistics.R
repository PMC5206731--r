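test_that("alignment distribution is a proper density", {
  # all mass at 1.0 lands in the top bin
  stk <- stackWithLengths(rep(1, 12))
  d <- alignmentDistribution(stk, binWidth = 0.05)
  expect_equal(sum(d$count), 12)
  expect_equal(d$count[nrow(d)], 12)
  expect_equal(sum(d$density * (d$bin_hi - d$bin_lo)), 1, tolerance = 1e-12)

  # arbitrary lengths: density integrates to 1, including with a bin width
  # that does not divide 1 (the trailing bin is narrower)
  lens <- withr::with_seed(21, runif(300))
  for (bw in c(0.05, 0.1, 0.3)) {
    d <- alignmentDistribution(stackWithLengths(lens), binWidth = bw)
    expect_equal(sum(d$density * (d$bin_hi - d$bin_lo)), 1,
                 tolerance = 1e-9)
    expect_equal(sum(d$count), 300)
  }

  # roughly flat for uniform lengths
  d <- alignmentDistribution(stackWithLengths(lens), binWidth = 0.25)
  expect_true(all(abs(d$density - 1) < 0.35))

  expect_error(alignmentDistribution(stackWithLengths(0.5), binWidth = 0),
               "binWidth")
})

test_that("statistics error when no cell is valid", {
  noSeg <- quantizeFibers(straightFiberTable(numeric(0), numeric(0),
                                             numeric(0), numeric(0)))
  fld <- computeField(noSeg, gridSpec(40, 40, circleRadius = 10))
  expect_error(meanAlignment(fld), "no valid cells")
  expect_error(alignmentDistribution(stackField(fld)), "no valid cells")
  expect_error(strongAlignmentRatio(fld), "no valid cells")
})

test_that("mean alignment is the arithmetic mean over valid cells", {
  expect_equal(meanAlignment(stackWithLengths(rep(1, 5))), 1)
  expect_equal(meanAlignment(stackWithLengths(c(0.2, 0.4))), 0.3)
  lens <- withr::with_seed(2, runif(40))
  expect_equal(meanAlignment(fieldWithLengths(lens)), mean(lens))
})

test_that("strong-alignment ratio counts strict exceedances", {
  stk <- stackWithLengths(c(0.8, 0.6, 0.9, 0.5))
  expect_equal(strongAlignmentRatio(stk, 0.7), 0.5)
  expect_equal(strongAlignmentRatio(stackWithLengths(rep(1, 7)), 0.7), 1)
  expect_equal(strongAlignmentRatio(stk, 1), 0)      # strict inequality
  expect_equal(strongAlignmentRatio(stackWithLengths(c(0.7, 0.7)), 0.7), 0)
  expect_error(strongAlignmentRatio(stk, 1.2), "threshold")
})

test_that("strong-alignment ratio is non-increasing in the threshold", {
  lens <- withr::with_seed(31, runif(200))
  stk <- stackWithLengths(lens)
  ths <- seq(0, 1, by = 0.05)
  ratios <- vapply(ths, function(t) strongAlignmentRatio(stk, t),
                   numeric(1))
  expect_true(all(diff(ratios) <= 0))
})

test_that("high-alignment filtering returns exactly the exceeding cells", {
  lens <- withr::with_seed(8, runif(50))
  fld <- fieldWithLengths(lens)
  stk <- stackField(fld)

  high <- filterHighAlignment(stk, 0.8)
  expect_identical(nrow(high), sum(lens > 0.8))
  expect_true(all(high$length > 0.8))
  expect_equal(unique(high$z_um), 1)  # z_index 1 at 1 um spacing

  expect_identical(nrow(filterHighAlignment(stk, 0)), length(lens))
  expect_identical(nrow(filterHighAlignment(stackWithLengths(rep(0.5, 9)),
                                            0.8)), 0L)
})

test_that("z pooling weights all slices equally", {
  f1 <- fieldWithLengths(c(0.2, 0.4))
  f2 <- fieldWithLengths(c(0.8, 0.9))
  f2@zIndex <- 2L
  stk <- stackField(list(f2, f1))  # constructor reorders by z
  expect_identical(vapply(stk@fields, function(f) f@zIndex, integer(1)),
                   1:2)
  expect_equal(meanAlignment(stk), mean(c(0.2, 0.4, 0.8, 0.9)))
  expect_equal(strongAlignmentRatio(stk, 0.7), 0.5)
})

test_that("circle-size sweep: counts grow with the radius, area-like", {
  seg <- latticeSegments(200, 200, step = 2, angle = 45)
  grid <- gridSpec(200, 200, spacing = 10, circleRadius = 25,
                   minFiberCount = 10)
  sw <- circleSizeSweep(seg, grid, c(15, 25, 35))
  expect_identical(nrow(sw), 3L)
  expect_true(all(diff(sw$mean_segment_count) > 0))
  # on a homogeneous field the count scales with circle area
  expect_equal(sw$mean_segment_count[2] / sw$mean_segment_count[1],
               (25 / 15)^2, tolerance = 0.12)
  expect_equal(sw$mean_alignment, rep(1, 3))

  expect_identical(nrow(circleSizeSweep(seg, grid, 25)), 1L)
  expect_error(circleSizeSweep(seg, grid, numeric(0)), "radii")
})

test_that("sweep on a radial field: alignment decreases, selection heuristic works", {
  ft <- simulateRadial(radialSimConfig(noiseStd = 20, seed = 17))
  seg <- quantizeFibers(ft, 5)
  grid <- gridSpec(512, 512, spacing = 20, circleRadius = 25,
                   minFiberCount = 5)
  sw <- circleSizeSweep(seg, grid, c(15, 35, 70, 140),
                        circularBoundary(c(0, 0), 150))
  # larger circles mix radial orientations: less apparent alignment
  expect_true(all(diff(sw$mean_alignment) < 0))
  expect_true(all(diff(sw$mean_segment_count) > 0))
  sel <- selectCircleRadius(sw, coverage = 0.5)
  expect_true(is.na(sel) || sel %in% sw$radius)
  expect_identical(selectCircleRadius(sw, coverage = 1.1), NA_real_)
})
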