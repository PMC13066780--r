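# squared k-space residual of one segment under a candidate transform
.segmentResidual <- function(x, theta, coils, lines, ySeg) {
  sum(Mod(encodeSegment(x, theta, coils, lines) - ySeg)^2)
}

# derivative-free pattern search over the 6 rigid parameters: coordinate
# steps of shrinking radius, accepting only improvements
.patternSearch <- function(x, theta, coils, lines, ySeg,
                           radiusMm, radiusDeg, nShrink, shrink,
                           maxSweeps = 6L) {
  p <- c(theta@translation, theta@rotation)
  best <- .segmentResidual(x, theta, coils, lines, ySeg)
  rad <- c(rep(radiusMm, 3), rep(radiusDeg, 3))
  for (k in seq_len(nShrink)) {
    for (sweep in seq_len(maxSweeps)) {
      improved <- FALSE
      for (j in seq_len(6L)) {
        if (rad[j] == 0) next
        for (sgn in c(1, -1)) {
          cand <- p
          cand[j] <- cand[j] + sgn * rad[j]
          val <- .segmentResidual(x, rigidTransform(cand[1:3], cand[4:6]),
                                  coils, lines, ySeg)
          if (val < best - 1e-12) {
            best <- val
            p <- cand
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    rad <- rad * shrink
  }
  list(transform = rigidTransform(p[1:3], p[4:6]), residual = best)
}

# CG image estimate from a subset of segments with their transforms
.subsetRecon <- function(ks, coils, thetas, keep, cgIters, dims) {
  b <- array(0i, dims)
  for (s in keep)
    b <- b + adjointSegment(ks@data[[s]], thetas[[s]], coils,
                            ks@lines[[s]])@data
  nop <- .mocoNormalOp(coils, ks@lines[keep], thetas[keep], dims)
  .cgSolve(nop, b, cgIters, 1e-8)$x
}

#' Alternating image/motion optimization (baseline)
#'
#' A simplified alternating joint optimizer in the style of the classic
#' sampling-order-based correction: it alternates (a) a CG image update
#' with the current motion estimate and (b) per-segment 6-parameter
#' updates minimizing that segment's k-space residual by a derivative-free
#' pattern search with shrinking step radius, visiting segments in seeded
#' random order each sweep.
#'
#' Each segment's motion update searches against a leave-one-out image
#' reconstructed from the other segments: a consensus image absorbs the
#' moving segment's inconsistency into ghosting that makes zero motion
#' spuriously optimal, while the leave-one-out reference leaves the
#' segment's misalignment visible to the residual. A candidate set of
#' transforms is only accepted if the total data-consistency residual
#' (after the subsequent image update) does not increase, so the reported
#' residual trace is non-increasing by construction. Comparisons with the
#' published alternating method are qualitative: its Newton-type updates
#' and temporal multiresolution are not reproduced.
#'
#' @param ks a [SegmentedKSpace-class].
#' @param coils a [CoilMaps-class].
#' @param outerIters alternation count; `0` returns the uncorrected CG
#'   reconstruction and an identity trajectory.
#' @param cgIters CG iterations per image update.
#' @param radiusMm,radiusDeg initial pattern-search radii (a zero radius
#'   freezes those parameters).
#' @param nShrink number of radius-shrink stages.
#' @param shrink radius multiplier per stage.
#' @param seed integer seed (segment visiting order).
#' @param tol relative residual-decrease tolerance: a smaller improvement
#'   counts as stagnation.
#' @return list with `volume` (complex [MRVolume-class]), `trajectory`
#'   ([MotionTrajectory-class], one state per segment), `residuals` (total
#'   data residual per outer iteration, non-increasing) and `converged`
#'   (TRUE when the loop stopped on stagnation rather than the iteration
#'   cap).
#' @export
alternatingMoco <- function(ks, coils, outerIters = 3L, cgIters = 5L,
                            radiusMm = 2, radiusDeg = 2, nShrink = 4L,
                            shrink = 0.5, seed = 1L, tol = 1e-4) {
  scheme <- ks@scheme
  nSeg <- nSegments(scheme)
  sps <- scheme@shotsPerSegment
  dims <- dim(coils@maps)[1:3]
  thetas <- replicate(nSeg, identityTransform())
  trajOf <- function(th) motionTrajectory(th, rep(seq_len(nSeg), each = sps))
  if (outerIters == 0L) {
    return(list(volume = uncorrectedRecon(ks, coils, nIters = cgIters),
                trajectory = trajOf(thetas),
                residuals = numeric(0), converged = NA))
  }
  total <- function(x, th) {
    sum(vapply(seq_len(nSeg), function(s)
      .segmentResidual(mrVolume(x, coils@spacing), th[[s]], coils,
                       ks@lines[[s]], ks@data[[s]]), numeric(1)))
  }
  x <- .subsetRecon(ks, coils, thetas, seq_len(nSeg), cgIters, dims)
  res <- total(x, thetas)
  resTrace <- res
  converged <- FALSE
  for (it in seq_len(outerIters)) {
    thetasNew <- thetas
    ord <- withSeed(seed + it, sample.int(nSeg))
    for (s in ord) {
      if (nSeg > 1L) {
        xloo <- .subsetRecon(ks, coils, thetasNew,
                             setdiff(seq_len(nSeg), s), cgIters, dims)
        ref <- mrVolume(xloo, coils@spacing)
      } else {
        ref <- mrVolume(x, coils@spacing)
      }
      fit <- .patternSearch(ref, thetasNew[[s]], coils, ks@lines[[s]],
                            ks@data[[s]], radiusMm, radiusDeg,
                            nShrink, shrink)
      thetasNew[[s]] <- fit$transform
    }
    xNew <- .subsetRecon(ks, coils, thetasNew, seq_len(nSeg), cgIters, dims)
    resNew <- total(xNew, thetasNew)
    if (resNew > res * (1 + 1e-12)) {      # reject: keep previous iterate
      converged <- TRUE
      break
    }
    stalled <- (res - resNew) < tol * (res + 1e-12)
    x <- xNew
    thetas <- thetasNew
    res <- resNew
    resTrace <- c(resTrace, res)
    if (stalled) {
      converged <- TRUE
      break
    }
  }
  list(volume = mrVolume(x, coils@spacing), trajectory = trajOf(thetas),
       residuals = resTrace, converged = converged)
}
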