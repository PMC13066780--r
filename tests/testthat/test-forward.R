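test_that("rigid resampling is exact on lattice-aligned cases", {
  v <- randComplexVolume(16L, seed = 21)
  expect_identical(volumeData(applyRigid(v, identityTransform())),
                   volumeData(v))
  sh <- applyRigid(v, rigidTransform(c(3, 0, 0)))
  expect_equal(volumeData(sh)[5:16, , ], volumeData(v)[2:13, , ],
               tolerance = 1e-14)
})

test_that("quarter-turn about z matches the array-rotation oracle", {
  n <- 16L
  ph <- makePhantom(n, seed = 2)
  rot <- applyRigid(ph, rigidTransform(rotation = c(0, 0, 90)))
  # oracle: out(i,j,k) = in(j, 2c - i, k) in 0-based centred coords
  c0 <- n %/% 2
  inner <- 2:(n - 1)                      # stay off the wrap-around edge
  arr <- volumeData(ph)
  oracle <- array(0, dim(arr))
  for (i in inner) for (j in inner) {
    src_x <- (j - 1 - c0) + c0 + 1
    src_y <- c0 - (i - 1 - c0) + 1
    if (src_y >= 1 && src_y <= n)
      oracle[i, j, ] <- arr[src_x, src_y, ]
  }
  expect_lt(max(abs(volumeData(rot)[inner, inner, inner] -
                    oracle[inner, inner, inner])), 1e-10)
})

test_that("encode reduces to the centred orthonormal FFT in the unit case", {
  n <- 16L
  v <- randComplexVolume(n, seed = 22)
  unit <- new("CoilMaps", maps = array(1 + 0i, c(n, n, n, 1L)),
              spacing = rep(1, 3))
  full <- as.matrix(expand.grid(0:(n - 1), 0:(n - 1)))
  enc <- encodeSegment(v, identityTransform(), unit, full)
  k <- fft3c(volumeData(v))
  expect_lt(max(Mod(enc[, , 1] - matrix(k, n, n * n))), 1e-12)
  # empty mask
  e0 <- encodeSegment(v, identityTransform(), unit,
                      matrix(integer(0), 0, 2))
  expect_equal(dim(e0), c(n, 0L, 1L))
})

test_that("Parseval holds for full-mask encoding with RSS coils", {
  n <- 16L
  v <- randComplexVolume(n, seed = 23)
  coils <- fixCoils(n, 3L)
  full <- as.matrix(expand.grid(0:(n - 1), 0:(n - 1)))
  th <- randTransform(31, tScale = 2, rScale = 15)
  xt <- applyRigid(v, th)@data
  enc <- encodeSegment(v, th, coils, full)
  lhs <- sum(Mod(enc)^2)
  rhs <- sum(vapply(1:3, function(c_)
    sum(Mod(coilArray(coils)[, , , c_] * xt)^2), numeric(1)))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("adjoint passes the dot test on random instances", {
  n <- 12L
  coils <- fixCoils(n, 3L, seed = 8)
  for (seed in 1:4) {
    sc <- generateDisorderScheme(n, n, nShots = 2L, tfeFactor = 36L,
                                 seed = seed)
    ln <- segmentLines(sc)[[1L]]
    th <- randTransform(seed + 60, tScale = 2, rScale = 20)
    x <- randComplexVolume(n, seed + 70)
    y <- withr::with_seed(seed + 80,
      array(complex(real = rnorm(n * nrow(ln) * 3),
                    imaginary = rnorm(n * nrow(ln) * 3)),
            c(n, nrow(ln), 3L)))
    Ax <- encodeSegment(x, th, coils, ln)
    Aty <- adjointSegment(y, th, coils, ln)
    lhs <- sum(Conj(y) * Ax)
    rhs <- sum(Conj(volumeData(Aty)) * volumeData(x))
    rel <- Mod(lhs - rhs) /
      (sqrt(sum(Mod(Ax)^2)) * sqrt(sum(Mod(y)^2)))
    expect_lt(rel, 1e-8)
  }
  # zero input maps to zero
  sc <- generateDisorderScheme(n, n, 2L, 36L, seed = 1)
  ln <- segmentLines(sc)[[1L]]
  z <- adjointSegment(array(0i, c(n, nrow(ln), 3L)),
                      randTransform(1), coils, ln)
  expect_equal(max(Mod(volumeData(z))), 0)
})

test_that("encode is linear in the image", {
  n <- 12L
  coils <- fixCoils(n, 2L, seed = 9)
  sc <- generateDisorderScheme(n, n, 2L, 36L, seed = 2)
  ln <- segmentLines(sc)[[1L]]
  th <- randTransform(90, tScale = 1, rScale = 10)
  a <- randComplexVolume(n, 91)
  b <- randComplexVolume(n, 92)
  both <- mrVolume(volumeData(a) + 2i * volumeData(b))
  lhs <- encodeSegment(both, th, coils, ln)
  rhs <- encodeSegment(a, th, coils, ln) +
    2i * encodeSegment(b, th, coils, ln)
  expect_lt(max(Mod(lhs - rhs)), 1e-10)
})

test_that("simulation is consistent with still encoding and seeded noise", {
  n <- 16L
  ph <- fixPhantom(n)
  coils <- fixCoils(n, 2L)
  sc <- fixScheme(n, nShots = 4L)
  still <- simulateAcquisition(ph, identityTrajectory(4L), sc, coils)
  for (s in 1:4) {
    direct <- encodeSegment(ph, identityTransform(), coils,
                            segmentLines(sc)[[s]])
    expect_lt(max(Mod(still@data[[s]] - direct)), 1e-12)
    expect_equal(dim(still@data[[s]]),
                 c(n, nrow(segmentLines(sc)[[s]]), 2L))
  }
  n1 <- simulateAcquisition(ph, identityTrajectory(4L), sc, coils,
                            noiseStd = 0.1, seed = 5)
  n2 <- simulateAcquisition(ph, identityTrajectory(4L), sc, coils,
                            noiseStd = 0.1, seed = 5)
  n3 <- simulateAcquisition(ph, identityTrajectory(4L), sc, coils,
                            noiseStd = 0.1, seed = 6)
  expect_identical(n1@data, n2@data)
  expect_false(identical(n1@data, n3@data))
})

test_that("a single motion state is equivalent to encoding the moved image", {
  n <- 16L
  ph <- fixPhantom(n)
  coil1 <- makeCoilMaps(n, 1L, seed = 5)
  sc <- fixScheme(n, nShots = 4L)
  th <- rigidTransform(c(1.5, -2, 0.8), c(4, -6, 3))
  ks <- simulateAcquisition(ph, motionTrajectory(list(th), rep(1L, 4L)),
                            sc, coil1)
  full <- array(0i, c(n, n, n))
  fm <- matrix(full, n, n * n)
  for (s in 1:4) {
    ln <- segmentLines(sc)[[s]]
    fm[, ln[, 1] + 1 + ln[, 2] * n] <- ks@data[[s]][, , 1]
  }
  img <- ifft3c(array(fm, c(n, n, n))) / coilArray(coil1)[, , , 1]
  expect_lt(max(Mod(img - volumeData(applyRigid(ph, th)))), 1e-10)
})

test_that("regrouping k-space preserves every sample", {
  n <- 16L
  ph <- fixPhantom(n)
  coils <- fixCoils(n, 2L)
  sc <- fixScheme(n, nShots = 4L, sps = 2L)
  traj <- sampleRandomTrajectory(2L, 1, 1, seed = 3, nShots = 4L)
  ks <- simulateAcquisition(ph, traj, sc, coils)
  re <- regroupKSpace(ks, 1L)
  expect_equal(nSegments(re), 4L)
  back <- regroupKSpace(re, 2L)
  expect_equal(back@data, ks@data)
})
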