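#' Create a motion trajectory
#'
#' @param states list of [RigidTransform-class] objects, in temporal order.
#' @param assignment integer vector mapping each shot (in acquisition order)
#'   to a state index; defaults to one shot per state.
#' @return a [MotionTrajectory-class].
#' @export
motionTrajectory <- function(states, assignment = seq_along(states)) {
  new("MotionTrajectory", states = states, assignment = as.integer(assignment))
}

#' Identity trajectory
#'
#' @param nStates number of (identity) states.
#' @param nShots number of shots; must be a multiple of `nStates`.
#' @return a [MotionTrajectory-class] whose states are all the identity.
#' @export
identityTrajectory <- function(nStates, nShots = nStates) {
  motionTrajectory(replicate(nStates, identityTransform()),
                   rep(seq_len(nStates), each = nShots %/% nStates))
}

#' Sample a random motion trajectory
#'
#' Draws each state's six parameters independently from zero-mean normal
#' distributions with per-axis standard deviations `transStdMm` (mm) and
#' `rotStdDeg` (degrees), the model used for random intersegment motion
#' ("spatially medium": 2 mm / 1 deg; "spatially extreme": 12 mm / 6 deg).
#'
#' @param nStates number of motion states.
#' @param transStdMm per-axis translation std in mm.
#' @param rotStdDeg per-axis rotation std in degrees.
#' @param seed integer seed (the generator is a pure function of its
#'   arguments).
#' @param nShots number of shots; must be a multiple of `nStates`. Shots are
#'   split contiguously and evenly over the states.
#' @return a [MotionTrajectory-class].
#' @export
sampleRandomTrajectory <- function(nStates, transStdMm, rotStdDeg, seed,
                                   nShots = nStates) {
  stopifnot(nStates >= 1, transStdMm >= 0, rotStdDeg >= 0,
            nShots %% nStates == 0)
  states <- withSeed(seed, {
    lapply(seq_len(nStates), function(i) {
      rigidTransform(rnorm(3, 0, transStdMm), rnorm(3, 0, rotStdDeg))
    })
  })
  motionTrajectory(states, rep(seq_len(nStates), each = nShots %/% nStates))
}

#' Refine a trajectory with intrasegment motion
#'
#' Replaces each original state by `nStates / length(states)` finer states,
#' each the composition of the original transform with an independent random
#' perturbation whose per-axis stds are `severityFraction` times the
#' original stds (e.g. 64 intersegment states refined to 320 per-shot states
#' at 1/16th severity).
#'
#' @param traj a [MotionTrajectory-class].
#' @param nStates total states after refinement (multiple of the original
#'   state count; each original state's shots must divide evenly).
#' @param severityFraction scale factor applied to the stds.
#' @param transStdMm,rotStdDeg the stds of the original trajectory.
#' @param seed integer seed.
#' @return a refined [MotionTrajectory-class].
#' @export
addIntrasegmentMotion <- function(traj, nStates, severityFraction,
                                  transStdMm, rotStdDeg, seed) {
  n0 <- length(traj@states)
  if (nStates %% n0 != 0)
    stop("nStates must be a multiple of the original state count")
  k <- nStates %/% n0
  shotsPerState <- as.integer(table(factor(traj@assignment, seq_len(n0))))
  if (any(shotsPerState %% k != 0))
    stop("each state's shots must divide evenly over the refined states")
  perturb <- withSeed(seed, {
    lapply(seq_len(nStates), function(i) {
      rigidTransform(rnorm(3, 0, severityFraction * transStdMm),
                     rnorm(3, 0, severityFraction * rotStdDeg))
    })
  })
  states <- vector("list", nStates)
  assignment <- integer(0)
  for (s in seq_len(n0)) {
    for (j in seq_len(k)) {
      idx <- (s - 1L) * k + j
      states[[idx]] <- composeTransforms(perturb[[idx]], traj@states[[s]])
      assignment <- c(assignment, rep(idx, shotsPerState[s] %/% k))
    }
  }
  motionTrajectory(states, assignment)
}

#' Scripted motion trajectories
#'
#' Generates the three volunteer-style motion patterns: `gradual` (slow
#' piecewise-linear drift between seeded waypoints), `jittery`
#' (piecewise-constant poses with abrupt seeded jumps every `jumpPeriod`
#' states), and `stepwise_extreme` (monotone progression of every parameter
#' from -amplitude to +amplitude in equal steps).
#'
#' @param pattern one of "gradual", "jittery", "stepwise_extreme".
#' @param nStates number of states (>= 2).
#' @param transAmpMm translation amplitude in mm.
#' @param rotAmpDeg rotation amplitude in degrees.
#' @param jumpPeriod states between jumps (jittery only).
#' @param seed integer seed.
#' @param nShots number of shots (multiple of `nStates`).
#' @return a [MotionTrajectory-class].
#' @export
scriptedTrajectory <- function(pattern = c("gradual", "jittery", "stepwise_extreme"),
                               nStates, transAmpMm = 0, rotAmpDeg = 0,
                               jumpPeriod = 4L, seed = 1L, nShots = nStates) {
  pattern <- match.arg(pattern)
  stopifnot(nStates >= 2)
  par <- switch(pattern,
    stepwise_extreme = {
      f <- seq(-1, 1, length.out = nStates)
      cbind(outer(f, rep(transAmpMm, 3)), outer(f, rep(rotAmpDeg, 3)))
    },
    gradual = withSeed(seed, {
      nWay <- max(3L, min(6L, nStates))
      way <- cbind(matrix(runif(nWay * 3, -transAmpMm, transAmpMm), nWay),
                   matrix(runif(nWay * 3, -rotAmpDeg, rotAmpDeg), nWay))
      way[1L, ] <- 0
      tWay <- seq(0, 1, length.out = nWay)
      tOut <- seq(0, 1, length.out = nStates)
      apply(way, 2L, function(col) approx(tWay, col, xout = tOut)$y)
    }),
    jittery = withSeed(seed, {
      nJumps <- ceiling(nStates / jumpPeriod)
      poses <- cbind(matrix(runif(nJumps * 3, -transAmpMm, transAmpMm), nJumps),
                     matrix(runif(nJumps * 3, -rotAmpDeg, rotAmpDeg), nJumps))
      poses[rep(seq_len(nJumps), each = jumpPeriod)[seq_len(nStates)], ,
            drop = FALSE]
    })
  )
  states <- lapply(seq_len(nStates), function(i)
    rigidTransform(par[i, 1:3], par[i, 4:6]))
  motionTrajectory(states, rep(seq_len(nStates), each = nShots %/% nStates))
}

#' Per-shot expansion of a trajectory
#'
#' @param traj a [MotionTrajectory-class].
#' @return list of [RigidTransform-class], one per shot.
#' @export
shotTransforms <- function(traj) traj@states[traj@assignment]

#' One transform per segment of a sampling scheme
#'
#' Maps a trajectory defined over shots to one state per segment (the state
#' of the segment's first shot; exact when motion is intersegment-only).
#'
#' @param traj a [MotionTrajectory-class] covering the scheme's shots.
#' @param scheme a [SamplingScheme-class].
#' @return list of [RigidTransform-class], one per segment.
#' @export
segmentTransformsOf <- function(traj, scheme) {
  sps <- scheme@shotsPerSegment
  if (length(traj@assignment) != scheme@nShots)
    stop("trajectory does not cover the scheme's shots")
  lapply(seq_len(nSegments(scheme)), function(s)
    traj@states[[traj@assignment[(s - 1L) * sps + 1L]]])
}

#' Remove the global rigid offset between two trajectories
#'
#' Groupwise registration leaves a gauge freedom: a single rigid transform
#' `g` composed into every state. This finds the `g` (translation in closed
#' form, rotation by iterative minimization started at the chordal mean)
#' minimizing the mean squared [transformDistance()] between
#' `compose(est_s, g)` and `ref_s` over per-shot expanded states, and
#' returns `est` with `g` composed in. The result's mean distance never
#' exceeds the input's.
#'
#' @param est,ref [MotionTrajectory-class] objects over the same shot count.
#' @param rotScaleMmPerDeg weight combining rotation (deg) with translation
#'   (mm) in the minimized cost.
#' @return a [MotionTrajectory-class] (same states/assignment structure as
#'   `est`, offset applied).
#' @export
removeGlobalOffset <- function(est, ref, rotScaleMmPerDeg = 1) {
  if (length(est@assignment) != length(ref@assignment))
    stop("trajectories must cover the same shots")
  es <- shotTransforms(est)
  rs <- shotTransforms(ref)
  Re_ <- lapply(es, rotationMatrix)
  Rr <- lapply(rs, rotationMatrix)
  # translation of g decouples: minimize sum over s of
  # || t_est_s + R_est_s t_g - t_ref_s ||^2
  tg <- rowMeans(vapply(seq_along(es), function(s)
    as.numeric(t(Re_[[s]]) %*% (rs[[s]]@translation - es[[s]]@translation)),
    numeric(3)))
  rotCost <- function(ang) {
    Rg <- rotationMatrix(rigidTransform(rotation = ang))
    sum(vapply(seq_along(es), function(s) {
      Rrel <- t(Rr[[s]]) %*% (Re_[[s]] %*% Rg)
      a <- acos(.clamp((sum(diag(Rrel)) - 1) / 2, -1, 1)) * 180 / pi
      (rotScaleMmPerDeg * a)^2
    }, numeric(1)))
  }
  rels <- lapply(seq_along(es), function(s)
    composeTransforms(invertTransform(es[[s]]), rs[[s]]))
  ang0 <- .meanTransform(rels)@rotation
  fit <- stats::optim(ang0, rotCost, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-12))
  gCand <- list(rigidTransform(tg, fit$par), identityTransform())
  score <- function(g) {
    d <- vapply(seq_along(es), function(s)
      transformDistance(composeTransforms(es[[s]], g), rs[[s]]), numeric(2))
    mean(d[1, ]^2) + rotScaleMmPerDeg^2 * mean(d[2, ]^2)
  }
  g <- gCand[[which.min(vapply(gCand, score, numeric(1)))]]
  motionTrajectory(lapply(est@states, composeTransforms, b = g),
                   est@assignment)
}

#' Monte-Carlo mean pairwise centre distance of random motion
#'
#' Samples independent rigid states from the random-motion model and
#' estimates the mean Euclidean distance between the transformed volume-
#' centre positions over all unordered state pairs (rotation about the
#' centre leaves the centre fixed, so the statistic probes the translation
#' distribution).
#'
#' @param transStdMm,rotStdDeg per-axis stds of the motion model.
#' @param nStates number of sampled states (`choose(nStates, 2)` pairs for
#'   `all_pairs`, `nStates / 2` pairs for `disjoint_pairs`).
#' @param seed integer seed.
#' @param method `all_pairs` averages every unordered state pair;
#'   `disjoint_pairs` averages independent pairs and scales to very large
#'   draws (both have the same expectation for i.i.d. states).
#' @return mean pairwise distance in mm.
#' @export
meanPairwiseCentreDistance <- function(transStdMm, rotStdDeg,
                                       nStates = 1000L, seed = 1L,
                                       method = c("all_pairs",
                                                  "disjoint_pairs")) {
  method <- match.arg(method)
  if (method == "all_pairs") {
    traj <- sampleRandomTrajectory(nStates, transStdMm, rotStdDeg, seed)
    centres <- t(vapply(traj@states, function(s) s@translation, numeric(3)))
    return(mean(stats::dist(centres)))
  }
  # disjoint pairs scale to very large draws: rotation about the centre
  # leaves the centre fixed, so only the translations enter the statistic
  withSeed(seed, {
    half <- nStates %/% 2L
    a <- matrix(rnorm(3L * half, 0, transStdMm), 3L)
    b <- matrix(rnorm(3L * half, 0, transStdMm), 3L)
    mean(sqrt(colSums((a - b)^2)))
  })
}
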