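# merge segments that share one transform: the masking projections add up,
# so their union behaves as a single segment (a large saving for the
# all-identity trajectory of the uncorrected reconstruction)
.groupByTransform <- function(thetas) {
  key <- vapply(thetas, function(th)
    paste(c(th@translation, th@rotation), collapse = "/"), character(1))
  unname(split(seq_along(thetas), factor(key, unique(key))))
}

# bind segment sample arrays (nx, m, nCoils) along the line dimension
.bindSamples <- function(samplesList) {
  if (length(samplesList) == 1L) return(samplesList[[1L]])
  d <- dim(samplesList[[1L]])
  m <- sum(vapply(samplesList, function(a) dim(a)[2L], integer(1)))
  out <- array(0i, c(d[1L], m, d[3L]))
  at <- 0L
  for (a in samplesList) {
    w <- dim(a)[2L]
    out[, (at + 1L):(at + w), ] <- a
    at <- at + w
  }
  out
}

# normal operator A^H A for the stacked per-segment forward model
.mocoNormalOp <- function(coils, linesList, thetas, dims) {
  colsList <- lapply(linesList, .lineCols, ny = dims[2L])
  nc <- nCoils(coils)
  function(x) {
    out <- array(0i, dims)
    for (s in seq_along(linesList)) {
      th <- thetas[[s]]
      xt <- applyRigid(mrVolume(x, coils@spacing), th)@data
      acc <- array(0i, dims)
      for (c_ in seq_len(nc)) {
        k <- matrix(fft3c(coils@maps[, , , c_] * xt), dims[1L],
                    dims[2L] * dims[3L])
        kz <- matrix(0i, dims[1L], dims[2L] * dims[3L])
        kz[, colsList[[s]]] <- k[, colsList[[s]]]
        acc <- acc + Conj(coils@maps[, , , c_]) * ifft3c(array(kz, dims))
      }
      out <- out + applyRigid(mrVolume(acc, coils@spacing), th,
                              adjoint = TRUE)@data
    }
    out
  }
}

#' Motion-corrected CG-SENSE reconstruction
#'
#' Solves `min_x || M F S C_theta x - y ||^2` via conjugate gradients on
#' the normal equations `A^H A x = A^H y`, where A stacks the per-segment
#' encoders with the trajectory's transforms. The estimated motion inverts
#' the displacements and rotations that occurred during acquisition.
#' Starts from `x0 = A^H y`; stops after `nIters` iterations or when the
#' relative normal-equation residual falls below `tol`. Basic CG, no
#' explicit regularizer; a Tikhonov term is available via `lambda`.
#'
#' @param ks a [SegmentedKSpace-class].
#' @param traj a [MotionTrajectory-class] covering the scheme's shots (one
#'   state per segment is used: the state of the segment's first shot).
#' @param coils a [CoilMaps-class].
#' @param nIters maximum CG iterations (10 suits clean simulations, 3 noisy
#'   data, where over-iteration amplifies noise).
#' @param tol relative residual tolerance.
#' @param lambda optional Tikhonov weight (default 0: plain least squares).
#' @return a complex [MRVolume-class]; attribute `residuals` holds the
#'   relative residual trace (non-increasing). Non-finite iterates are
#'   flagged with a warning and the last finite iterate returned.
#' @export
motionCorrectedCgSense <- function(ks, traj, coils, nIters = 10L,
                                   tol = 1e-6, lambda = 0) {
  dims <- dim(coils@maps)[1:3]
  thetas <- segmentTransformsOf(traj, ks@scheme)
  groups <- .groupByTransform(thetas)
  gLines <- lapply(groups, function(idx) do.call(rbind, ks@lines[idx]))
  gThetas <- lapply(groups, function(idx) thetas[[idx[1L]]])
  b <- array(0i, dims)
  for (g in seq_along(groups))
    b <- b + adjointSegment(.bindSamples(ks@data[groups[[g]]]),
                            gThetas[[g]], coils, gLines[[g]])@data
  nop <- .mocoNormalOp(coils, gLines, gThetas, dims)
  nopReg <- if (lambda > 0) function(x) nop(x) + lambda * x else nop
  sol <- .cgSolve(nopReg, b, nIters, tol)
  out <- mrVolume(sol$x, coils@spacing)
  attr(out, "residuals") <- sol$residuals
  out
}

#' Uncorrected CG-SENSE reconstruction
#'
#' The zero-motion baseline: [motionCorrectedCgSense()] with an
#' all-identity trajectory.
#'
#' @inheritParams motionCorrectedCgSense
#' @return a complex [MRVolume-class].
#' @export
uncorrectedRecon <- function(ks, coils, nIters = 10L, tol = 1e-6,
                             lambda = 0) {
  motionCorrectedCgSense(ks, identityTrajectory(1L, ks@scheme@nShots),
                         coils, nIters = nIters, tol = tol, lambda = lambda)
}

# Fourier-crop a k-space world by an integer factor: segment data keep the
# central lines (re-indexed), readout keeps the central rows, and coil maps
# are sinc-decimated through the same centred-FFT crop, so the cropped
# encode operator is the restriction of the full one.
.cropWorld <- function(data, linesList, coils, factor = 2L) {
  dims <- dim(coils@maps)[1:3]
  nd <- dims %/% factor
  lo <- floor(dims / 2) - floor(nd / 2)          # 0-based crop origin
  rows <- (lo[1L] + 1L):(lo[1L] + nd[1L])
  cmaps <- array(0i, c(nd, dim(coils@maps)[4L]))
  for (c_ in seq_len(dim(coils@maps)[4L])) {
    k <- fft3c(coils@maps[, , , c_])
    cmaps[, , , c_] <- ifft3c(k[rows, (lo[2L] + 1L):(lo[2L] + nd[2L]),
                                (lo[3L] + 1L):(lo[3L] + nd[3L])]) *
      sqrt(prod(nd) / prod(dims))
  }
  ccoils <- new("CoilMaps", maps = cmaps, spacing = coils@spacing * factor)
  cdata <- vector("list", length(data))
  clines <- vector("list", length(data))
  for (s_ in seq_along(data)) {
    ln <- linesList[[s_]]
    keep <- ln[, 1L] >= lo[2L] & ln[, 1L] < lo[2L] + nd[2L] &
            ln[, 2L] >= lo[3L] & ln[, 2L] < lo[3L] + nd[3L]
    clines[[s_]] <- cbind(ln[keep, 1L] - lo[2L], ln[keep, 2L] - lo[3L])
    storage.mode(clines[[s_]]) <- "integer"
    cdata[[s_]] <- data[[s_]][rows, keep, , drop = FALSE]
  }
  list(data = cdata, lines = clines, coils = ccoils)
}

#' Data-consistency refinement of a motion trajectory
#'
#' Polishes a per-segment motion estimate (e.g. the groupwise-registration
#' output) by minimizing each segment's k-space residual
#' `|| M_s F S C_theta x_ref - y_s ||^2` with a shrinking-radius pattern
#' search, where the reference `x_ref` is the motion-corrected CG
#' reconstruction under the current estimates, rebuilt every pass. A
#' moderately iterated CG reference does not absorb an individual
#' segment's inconsistency (that lives in slowly converging, high
#' g-factor modes), so each segment's residual keeps a clean minimum at
#' its true state; zero-filled leave-one-out references do not work here
#' because their spectrum is missing exactly the lines being compared.
#'
#' The search operates in the measured-data domain and is therefore
#' insensitive to the aliasing that limits image-domain registration of
#' extremely undersampled segment reconstructions; conversely it needs a
#' starting point within its search radius, which the registration
#' provides. For speed the refinement works in an SVD-compressed virtual
#' coil basis, and all passes except the last run in a Fourier-cropped
#' (half-resolution) k-space world where every evaluation is an order of
#' magnitude cheaper; the final pass polishes at full resolution.
#'
#' @param ks a [SegmentedKSpace-class].
#' @param coils a [CoilMaps-class].
#' @param traj0 initial [MotionTrajectory-class] (one state per segment).
#' @param radiusSchedule initial pattern-search radius (mm and degrees)
#'   for each pass; its length sets the number of passes.
#' @param nShrink radius halvings within each pass.
#' @param cgIters CG iterations for each pass's reference reconstruction.
#' @param searchCoils virtual coils retained for the refinement.
#' @param seed integer seed (segment visiting order).
#' @return the refined [MotionTrajectory-class].
#' @export
refineTrajectory <- function(ks, coils, traj0,
                             radiusSchedule = c(1.5, 0.75, 0.4, 0.25, 0.2),
                             nShrink = 2L, cgIters = 5L, searchCoils = 3L,
                             seed = 1L) {
  scheme <- ks@scheme
  nSeg <- nSegments(scheme)
  sps <- scheme@shotsPerSegment
  thetas <- segmentTransformsOf(traj0, scheme)
  if (nSeg < 2L) return(traj0)
  dims <- dim(coils@maps)[1:3]
  # virtual-coil compression of maps and data (orthonormal projection, so
  # residual ordering is preserved up to the discarded noise subspace)
  k <- min(searchCoils, nCoils(coils))
  C <- t(matrix(coils@maps, prod(dims), nCoils(coils)))
  U <- svd(C, nu = k, nv = 0)$u
  vmaps <- array(t(Conj(t(U)) %*% C), c(dims, k))
  vcoils <- new("CoilMaps", maps = vmaps, spacing = coils@spacing)
  vdata <- lapply(ks@data, function(y) {
    d <- dim(y)
    array(matrix(y, d[1L] * d[2L], d[3L]) %*% Conj(U), c(d[1L], d[2L], k))
  })
  cropped <- if (min(dims) >= 32L)
    .cropWorld(vdata, ks@lines, vcoils, 2L) else NULL
  nPass <- length(radiusSchedule)
  for (pass in seq_len(nPass)) {
    coarse <- !is.null(cropped) && pass < nPass
    wData <- if (coarse) cropped$data else vdata
    wLines <- if (coarse) cropped$lines else ks@lines
    wCoils <- if (coarse) cropped$coils else vcoils
    wDims <- dim(wCoils@maps)[1:3]
    groups <- .groupByTransform(thetas)
    gLines <- lapply(groups, function(idx) do.call(rbind, wLines[idx]))
    gThetas <- lapply(groups, function(idx) thetas[[idx[1L]]])
    b <- array(0i, wDims)
    for (g in seq_along(groups))
      b <- b + adjointSegment(.bindSamples(wData[groups[[g]]]),
                              gThetas[[g]], wCoils, gLines[[g]])@data
    nop <- .mocoNormalOp(wCoils, gLines, gThetas, wDims)
    ref <- mrVolume(.cgSolve(nop, b, cgIters, 1e-8)$x, wCoils@spacing)
    rad <- radiusSchedule[pass]
    ord <- withSeed(seed + pass, sample.int(nSeg))
    for (s_ in ord) {
      fit <- .patternSearch(ref, thetas[[s_]], wCoils, wLines[[s_]],
                            wData[[s_]], rad, rad, nShrink, 0.5)
      thetas[[s_]] <- fit$transform
    }
  }
  # gauge: a common transform composed into every state only changes the
  # reconstruction frame; fix it so the mean transform is the identity
  gm <- invertTransform(.meanTransform(thetas))
  thetas <- lapply(thetas, composeTransforms, b = gm)
  # model selection against the zero-motion null: score both trajectories
  # by the leave-one-out cross-validated data residual (each segment's
  # residual against a reconstruction from the other segments only, which
  # a consensus reconstruction cannot absorb) and keep the better. On
  # still data this returns the exact zero-motion trajectory, so the
  # corrected and uncorrected reconstructions coincide.
  looWorld <- if (min(dims) >= 64L) .cropWorld(vdata, ks@lines, vcoils, 4L)
              else if (!is.null(cropped)) cropped
              else list(data = vdata, lines = ks@lines, coils = vcoils)
  looScore <- function(th) {
    wDims <- dim(looWorld$coils@maps)[1:3]
    sum(vapply(seq_len(nSeg), function(s_) {
      keep <- setdiff(seq_len(nSeg), s_)
      b <- array(0i, wDims)
      for (t_ in keep)
        b <- b + adjointSegment(looWorld$data[[t_]], th[[t_]],
                                looWorld$coils, looWorld$lines[[t_]])@data
      nop <- .mocoNormalOp(looWorld$coils, looWorld$lines[keep], th[keep],
                           wDims)
      ref <- mrVolume(.cgSolve(nop, b, 4L, 1e-8)$x, looWorld$coils@spacing)
      .segmentResidual(ref, th[[s_]], looWorld$coils, looWorld$lines[[s_]],
                       looWorld$data[[s_]])
    }, numeric(1)))
  }
  idThetas <- replicate(nSeg, identityTransform())
  if (looScore(idThetas) <= looScore(thetas)) thetas <- idThetas
  motionTrajectory(thetas, rep(seq_len(nSeg), each = sps))
}
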