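test_that("single shot covers a tiny plane exactly once", {
  sc <- generateDisorderScheme(4, 4, nShots = 1, tfeFactor = 16, seed = 1)
  lines <- shotOrder(sc)[[1]]
  expect_equal(nrow(lines), 16L)
  key <- lines[, 1] + 4 * lines[, 2]
  expect_setequal(key, 0:15)
})

test_that("checkered property holds exhaustively on a small grid", {
  sc <- generateDisorderScheme(8, 8, nShots = 4, tfeFactor = 16, seed = 7)
  masks <- segmentMasks(regroupScheme(sc, 1L))
  expect_length(masks, 4L)
  # pairwise disjoint, union covers the plane
  tot <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  expect_true(all(tot == 1L))
  # each 2x2 tile holds exactly one location per shot
  for (m in masks) {
    for (ty in 1:4) for (tz in 1:4) {
      tile <- m[(2 * ty - 1):(2 * ty), (2 * tz - 1):(2 * tz)]
      expect_equal(sum(tile), 1L)
    }
  }
})

test_that("full-scale scheme has the published line counts per segment", {
  sc <- generateDisorderScheme(240, 240, nShots = 320, tfeFactor = 180,
                               shotsPerSegment = 5L, seed = 1)
  expect_equal(nShots(sc) * sc@tfeFactor, 240L * 240L)  # full coverage
  ln <- segmentLines(sc)
  expect_length(ln, 64L)
  expect_true(all(vapply(ln, nrow, integer(1)) == 900L))
  # each shot spans low and high frequencies: every shot touches both the
  # central quarter-plane and the outer half of the plane
  centre <- c(120, 120)
  for (s in c(1L, 160L, 320L)) {
    r <- sqrt((shotOrder(sc)[[s]][, 1] - centre[1])^2 +
              (shotOrder(sc)[[s]][, 2] - centre[2])^2)
    expect_lt(min(r), 30)
    expect_gt(max(r), 90)
  }
})

test_that("216-line shots grouped three per segment give 648 lines", {
  sc <- generateDisorderScheme(216, 240, nShots = 12, tfeFactor = 216,
                               shotsPerSegment = 3L, seed = 2)
  expect_true(all(vapply(segmentLines(sc), nrow, integer(1)) == 648L))
})

test_that("partition property holds for random schemes including undersampled", {
  for (seed in 1:4) {
    nShots <- c(4L, 6L, 8L, 10L)[seed]
    sc <- generateDisorderScheme(16, 20, nShots = nShots, tfeFactor = 20,
                                 shotsPerSegment = 2L, seed = seed)
    masks <- segmentMasks(sc)
    tot <- Reduce(`+`, lapply(masks, function(m) m * 1L))
    expect_true(all(tot <= 1L))
    expect_equal(sum(tot), nShots * 20L)
  }
})

test_that("schemes are deterministic in the seed", {
  a <- generateDisorderScheme(16, 16, 4, 32, 2L, seed = 11)
  b <- generateDisorderScheme(16, 16, 4, 32, 2L, seed = 11)
  c <- generateDisorderScheme(16, 16, 4, 32, 2L, seed = 12)
  expect_identical(shotOrder(a), shotOrder(b))
  expect_false(identical(shotOrder(a), shotOrder(c)))
})

test_that("capacity and tiling violations are signalled", {
  expect_error(generateDisorderScheme(8, 8, nShots = 5, tfeFactor = 16),
               "capacity")
  expect_error(generateDisorderScheme(8, 8, nShots = 1, tfeFactor = 17),
               "tiling")
  expect_error(generateDisorderScheme(8, 8, nShots = 3, tfeFactor = 16,
                                      shotsPerSegment = 2L),
               "divisible")
})

test_that("one segment per scheme yields the full sampled set", {
  sc <- fixScheme(16L, nShots = 4L, tfe = 64L, sps = 4L)
  masks <- segmentMasks(sc)
  expect_length(masks, 1L)
  expect_equal(sum(masks[[1]]), 4L * 64L)
})

test_that("shot discarding accelerates as requested", {
  sc <- generateDisorderScheme(240, 240, nShots = 320, tfeFactor = 180,
                               shotsPerSegment = 5L, seed = 1)
  acc <- accelerateByShotDiscarding(sc, R = 4, seed = 5)
  expect_equal(nShots(acc), 80L)
  expect_identical(accelerateByShotDiscarding(sc, 1), sc)
  # retained shots keep their original within-shot ordering
  keyOrig <- lapply(shotOrder(sc), function(m) paste(m[, 1], m[, 2]))
  keyAcc <- lapply(shotOrder(acc), function(m) paste(m[, 1], m[, 2]))
  expect_true(all(vapply(keyAcc, function(k)
    any(vapply(keyOrig, identical, logical(1), k)), logical(1))))
})

test_that("shot discarding is deterministic and bounded", {
  sc <- fixScheme(16L, nShots = 8L, tfe = 32L)
  a <- accelerateByShotDiscarding(sc, 2, seed = 9)
  b <- accelerateByShotDiscarding(sc, 2, seed = 9)
  expect_identical(shotOrder(a), shotOrder(b))
  expect_equal(nShots(a), 4L)
  expect_error(accelerateByShotDiscarding(sc, 100), "too large")
})

test_that("scheme JSON round-trips", {
  sc <- fixScheme(16L, nShots = 4L, tfe = 32L, sps = 2L)
  path <- tempfile(fileext = ".json")
  writeScheme(sc, path)
  rt <- readScheme(path)
  expect_identical(shotOrder(rt), shotOrder(sc))
  expect_equal(rt@shotsPerSegment, sc@shotsPerSegment)
})
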