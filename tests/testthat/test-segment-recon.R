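test_that("zero-filled recon recovers a fully sampled single-coil image", {
  n <- 16L
  ph <- fixPhantom(n)
  coil1 <- makeCoilMaps(n, 1L, seed = 5)
  full <- as.matrix(expand.grid(0:(n - 1), 0:(n - 1)))
  y <- encodeSegment(ph, identityTransform(), coil1, full)
  rec <- zeroFilledRecon(y, coil1, full)
  expect_lt(max(abs(volumeData(rec) - volumeData(ph))), 1e-8)
  # all-zero input gives a zero volume
  z <- zeroFilledRecon(array(0i, dim(y)), coil1, full)
  expect_equal(max(volumeData(z)), 0)
})

test_that("undersampled zero-filled recon loses energy (projection)", {
  n <- 16L
  ph <- fixPhantom(n)
  coils <- fixCoils(n, 2L)
  sc <- fixScheme(n, nShots = 8L, tfe = 32L)   # 1/8 of the plane
  ks <- simulateAcquisition(ph, identityTrajectory(8L), sc, coils)
  full <- as.matrix(expand.grid(0:(n - 1), 0:(n - 1)))
  yFull <- encodeSegment(ph, identityTransform(), coils, full)
  normFull <- sqrt(sum(volumeData(
    zeroFilledRecon(yFull, coils, full))^2))
  normSeg <- sqrt(sum(volumeData(
    zeroFilledRecon(ks@data[[1]], coils, ks@lines[[1]]))^2))
  expect_lt(normSeg, normFull)
})

test_that("CG-Tikhonov recon approaches the well-posed limit", {
  n <- 16L
  ph <- fixPhantom(n)
  coils <- fixCoils(n, 2L)
  full <- as.matrix(expand.grid(0:(n - 1), 0:(n - 1)))
  y <- encodeSegment(ph, identityTransform(), coils, full)
  rec <- cgTikhonovSegmentRecon(y, coils, full, lambda = 1e-8,
                                nIters = 20L)
  expect_lt(max(abs(volumeData(rec) - volumeData(ph))), 1e-4)
  # residual trace is non-increasing
  res <- attr(rec, "residuals")
  expect_true(all(diff(res) <= 1e-12))
  # strong regularization shrinks the solution
  big <- cgTikhonovSegmentRecon(y, coils, full, lambda = 1e6, nIters = 10L)
  expect_lt(sqrt(sum(volumeData(big)^2)),
            1e-3 * sqrt(sum(volumeData(rec)^2)))
})

test_that("learned recon interface passes through and validates grids", {
  n <- 16L
  ph <- fixPhantom(n)
  coils <- fixCoils(n, 2L)
  sc <- fixScheme(n, nShots = 4L)
  ks <- simulateAcquisition(ph, identityTrajectory(4L), sc, coils)
  zf <- zeroFilledRecon(ks@data[[1]], coils, ks@lines[[1]])
  lr <- learnedSegmentRecon(ks@data[[1]], coils, ks@lines[[1]],
                            model = identity)
  expect_equal(volumeData(lr), volumeData(zf))
  badModel <- function(v) mrVolume(array(0, c(4, 4, 4)))
  expect_error(learnedSegmentRecon(ks@data[[1]], coils, ks@lines[[1]],
                                   model = badModel), "grid mismatch")
})

test_that("reconstructSegments dispatches per segment", {
  n <- 16L
  ph <- fixPhantom(n)
  coils <- fixCoils(n, 2L)
  sc <- fixScheme(n, nShots = 4L)
  ks <- simulateAcquisition(ph, identityTrajectory(4L), sc, coils)
  sr <- reconstructSegments(ks, coils, method = "zero_filled")
  expect_s4_class(sr, "SegmentReconstruction")
  expect_equal(nSegments(sr), 4L)
  for (s in 1:4) {
    direct <- zeroFilledRecon(ks@data[[s]], coils, ks@lines[[s]])
    expect_equal(volumeData(segmentVolumes(sr)[[s]]), volumeData(direct))
  }
  # segment reconstructions preserve gross anatomy on still data
  ph24 <- makePhantom(24L, seed = 1)
  coils24 <- makeCoilMaps(24L, 3L, seed = 2)
  sc24 <- generateDisorderScheme(24, 24, 4L, 144L, 1L, seed = 3)
  ks24 <- simulateAcquisition(ph24, identityTrajectory(4L), sc24, coils24)
  srcg <- reconstructSegments(ks24, coils24, method = "cg_tikhonov",
                              nIters = 8L)
  for (s in 1:4) {
    ncc <- cor(as.vector(volumeData(segmentVolumes(srcg)[[s]])),
               as.vector(volumeData(ph24)))
    expect_gt(ncc, 0.5)
  }
})
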