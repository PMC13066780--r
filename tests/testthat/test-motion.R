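test_that("rigid transforms satisfy the group axioms", {
  for (seed in 1:5) {
    a <- randTransform(seed)
    b <- randTransform(seed + 100)
    c_ <- randTransform(seed + 200)
    id <- identityTransform()
    expect_equal(composeTransforms(id, a)@translation, a@translation,
                 tolerance = 1e-10)
    expect_equal(composeTransforms(id, a)@rotation, a@rotation,
                 tolerance = 1e-10)
    inv <- composeTransforms(a, invertTransform(a))
    expect_lt(max(abs(c(inv@translation, inv@rotation))), 1e-10)
    lhs <- composeTransforms(composeTransforms(a, b), c_)
    rhs <- composeTransforms(a, composeTransforms(b, c_))
    expect_lt(max(abs(lhs@translation - rhs@translation)), 1e-10)
    expect_lt(max(abs(rotationMatrix(lhs) - rotationMatrix(rhs))), 1e-10)
  }
})

test_that("composition matches the 3x3 matrix-product oracle", {
  for (seed in 1:5) {
    a <- randTransform(seed, tScale = 0)
    b <- randTransform(seed + 50, tScale = 0)
    expect_equal(rotationMatrix(composeTransforms(a, b)),
                 rotationMatrix(a) %*% rotationMatrix(b),
                 tolerance = 1e-12)
  }
})

test_that("transform distance has the expected analytic values", {
  a <- rigidTransform(c(2, 0, 0))
  expect_equal(unname(transformDistance(a, identityTransform())),
               c(2, 0), tolerance = 1e-12)
  b <- randTransform(3)
  expect_equal(unname(transformDistance(b, b)), c(0, 0), tolerance = 1e-10)
  # geodesic angle equals the trace formula computed independently
  for (seed in 10:14) {
    x <- randTransform(seed)
    y <- randTransform(seed + 30)
    Rrel <- t(rotationMatrix(y)) %*% rotationMatrix(x)
    expect_equal(transformDistance(x, y)[["rot_deg"]],
                 acos(pmin(pmax((sum(diag(Rrel)) - 1) / 2, -1), 1)) * 180 / pi,
                 tolerance = 1e-10)
  }
})

test_that("transform distance is symmetric and satisfies the triangle inequality", {
  for (seed in 1:8) {
    a <- randTransform(seed)
    b <- randTransform(seed + 40)
    c_ <- randTransform(seed + 80)
    dab <- transformDistance(a, b)
    dba <- transformDistance(b, a)
    expect_equal(unname(dab), unname(dba), tolerance = 1e-10)
    dac <- transformDistance(a, c_)
    dcb <- transformDistance(c_, b)
    expect_lte(dab[["rot_deg"]], dac[["rot_deg"]] + dcb[["rot_deg"]] + 1e-9)
    expect_lte(dab[["trans_mm"]],
               transformDistance(a, c_)[["trans_mm"]] +
                 transformDistance(c_, b)[["trans_mm"]] + 1e-9)
  }
})

test_that("random trajectories are seeded draws with the requested statistics", {
  z <- sampleRandomTrajectory(5L, 0, 0, seed = 1)
  for (s in motionStates(z))
    expect_equal(c(s@translation, s@rotation), rep(0, 6))
  a <- sampleRandomTrajectory(50L, 2, 1, seed = 4)
  b <- sampleRandomTrajectory(50L, 2, 1, seed = 4)
  expect_equal(motionStates(a), motionStates(b))
  big <- sampleRandomTrajectory(4000L, 2, 1, seed = 5)
  tr <- vapply(motionStates(big), translation, numeric(3))
  ro <- vapply(motionStates(big), rotation, numeric(3))
  expect_equal(sd(as.vector(tr)), 2, tolerance = 0.05)
  expect_equal(sd(as.vector(ro)), 1, tolerance = 0.05)
})

test_that("mean pairwise centre distance matches the 3D Gaussian closed form", {
  # difference of two iid N(0, s^2 I3) translations has per-axis std s*sqrt(2);
  # the mean norm of a 3D Gaussian is sigma * 2 * sqrt(2/pi)
  closedForm <- function(s) s * sqrt(2) * 2 * sqrt(2 / pi)
  est <- meanPairwiseCentreDistance(2, 1, nStates = 800L, seed = 2)
  expect_equal(est, closedForm(2), tolerance = 0.02)
  est2 <- meanPairwiseCentreDistance(12, 6, nStates = 800L, seed = 3)
  expect_equal(est2, closedForm(12), tolerance = 0.02)
})

test_that("intrasegment refinement composes scaled perturbations", {
  base <- sampleRandomTrajectory(8L, 2, 1, seed = 6, nShots = 40L)
  same <- addIntrasegmentMotion(base, 40L, 0, 2, 1, seed = 7)
  expect_length(motionStates(same), 40L)
  for (i in seq_len(40L)) {
    orig <- motionStates(base)[[(i - 1) %/% 5 + 1]]
    d <- transformDistance(motionStates(same)[[i]], orig)
    expect_lt(max(d), 1e-5)
  }
  fine <- addIntrasegmentMotion(base, 40L, 1 / 16, 2, 1, seed = 7)
  expect_identical(
    motionStates(addIntrasegmentMotion(base, 40L, 1 / 16, 2, 1, seed = 7)),
    motionStates(fine))
  # empirical std of the added components is severity * std
  big <- addIntrasegmentMotion(sampleRandomTrajectory(1L, 0, 0, seed = 1,
                                                      nShots = 3000L),
                               3000L, 1 / 16, 2, 1, seed = 8)
  pb <- vapply(motionStates(big), function(s) c(s@translation, s@rotation),
               numeric(6))
  expect_equal(sd(as.vector(pb[1:3, ])), 2 / 16, tolerance = 0.03)
  expect_equal(sd(as.vector(pb[4:6, ])), 1 / 16, tolerance = 0.03)
})

test_that("scripted trajectories have their defining shapes", {
  z <- scriptedTrajectory("stepwise_extreme", 16L, 0, 0)
  for (s in motionStates(z))
    expect_equal(c(s@translation, s@rotation), rep(0, 6))
  st <- scriptedTrajectory("stepwise_extreme", 64L, 5, 10)
  rz <- vapply(motionStates(st), function(s) s@rotation[1], numeric(1))
  expect_equal(rz[1], -10)
  expect_equal(rz[64], 10)
  expect_true(all(diff(rz) > 0))
  ji <- scriptedTrajectory("jittery", 21L, 2, 2, jumpPeriod = 4L, seed = 3)
  poses <- unique(t(vapply(motionStates(ji), function(s)
    c(s@translation, s@rotation), numeric(6))))
  expect_equal(nrow(poses), ceiling(21 / 4))
  gr <- scriptedTrajectory("gradual", 32L, 3, 3, seed = 4)
  expect_length(motionStates(gr), 32L)
})

test_that("global-offset removal beats a coarse grid-search oracle", {
  ref <- sampleRandomTrajectory(6L, 1, 2, seed = 9)
  g0 <- rigidTransform(c(1, -1, 0), c(2, 0, -2))
  est <- motionTrajectory(lapply(motionStates(ref), function(s)
    composeTransforms(composeTransforms(
      rigidTransform(rnorm(3, 0, 0.1), rnorm(3, 0, 0.1)), s), g0)), 1:6)
  score <- function(states, g) {
    mean(vapply(seq_along(states), function(s) {
      d <- transformDistance(composeTransforms(states[[s]], g),
                             motionStates(ref)[[s]])
      d[["trans_mm"]]^2 + d[["rot_deg"]]^2
    }, numeric(1)))
  }
  # coarse 6-D grid oracle around the inverse offset
  grid <- seq(-2.5, 2.5, by = 0.5)
  bestGrid <- Inf
  for (tx in grid) for (rz in grid) {
    g <- rigidTransform(c(tx, 1, 0), c(-2, 0, rz))
    bestGrid <- min(bestGrid, score(motionStates(est), g))
  }
  aligned <- removeGlobalOffset(est, ref)
  achieved <- mean(vapply(1:6, function(s) {
    d <- transformDistance(motionStates(aligned)[[s]],
                           motionStates(ref)[[s]])
    d[["trans_mm"]]^2 + d[["rot_deg"]]^2
  }, numeric(1)))
  expect_lte(achieved, bestGrid + 1e-8)
})

test_that("global-offset removal is exact on pure gauge cases", {
  ref <- sampleRandomTrajectory(8L, 2, 2, seed = 12)
  expect_lt(max(abs(trajectoryError(ref, ref))), 1e-4)
  g <- rigidTransform(c(3, -1, 2), c(5, 8, -4))
  est <- motionTrajectory(lapply(motionStates(ref), composeTransforms,
                                 b = g), 1:8)
  expect_lt(max(abs(trajectoryError(est, ref))), 1e-5)
})

test_that("trajectory JSON round-trips with its convention", {
  traj <- sampleRandomTrajectory(4L, 2, 3, seed = 13, nShots = 8L)
  path <- tempfile(fileext = ".json")
  writeTrajectory(traj, path)
  rt <- readTrajectory(path)
  expect_equal(shotAssignment(rt), shotAssignment(traj))
  for (i in 1:4) {
    expect_equal(motionStates(rt)[[i]]@translation,
                 motionStates(traj)[[i]]@translation, tolerance = 1e-12)
    expect_equal(motionStates(rt)[[i]]@rotation,
                 motionStates(traj)[[i]]@rotation, tolerance = 1e-12)
  }
})
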