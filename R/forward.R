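#' Apply a rigid transform to a volume
#'
#' Resamples the volume under the transform (rotation about the grid centre
#' at 0-based index floor(dim/2), then translation) with trilinear
#' interpolation; samples falling outside the grid are zero. Complex data
#' are resampled component-wise. `adjoint = TRUE` applies the exact
#' transpose of the interpolation operator instead (the adjoint needed by
#' CG), scattering each voxel back onto its eight source neighbours.
#'
#' Rotations assume isotropic in-plane geometry: translations are converted
#' from mm to voxels per axis, rotations act in voxel space.
#'
#' @param vol an [MRVolume-class].
#' @param transform a [RigidTransform-class].
#' @param adjoint apply the transpose operator instead of the resampling.
#' @return an [MRVolume-class] on the same grid.
#' @export
applyRigid <- function(vol, transform, adjoint = FALSE) {
  d <- dim(vol@data)
  if (identical(transform@rotation, c(0, 0, 0)) &&
      identical(transform@translation, c(0, 0, 0))) return(vol)
  R <- rotationMatrix(transform)
  tvox <- transform@translation / vol@spacing
  centre <- floor(d / 2)
  fun <- if (adjoint) .resampleRigidAdjointC else .resampleRigidC
  run <- function(a) array(fun(as.numeric(a), as.integer(d),
                               as.numeric(R), as.numeric(tvox),
                               as.numeric(centre)), d)
  out <- if (is.complex(vol@data)) {
    complex(real = run(Re(vol@data)), imaginary = run(Im(vol@data)))
  } else {
    run(vol@data)
  }
  initialize(vol, data = array(out, d))
}

#' Encode one k-space segment (forward operator)
#'
#' Applies A = M F S C_theta to a volume: rigid-transforms the image,
#' multiplies by each coil map, takes the centred orthonormal 3D FFT, and
#' extracts the segment's phase-encode lines at all readout positions.
#'
#' @param vol complex or real [MRVolume-class] image x.
#' @param transform the segment's [RigidTransform-class].
#' @param coils a [CoilMaps-class] on the same grid.
#' @param lines integer matrix (m x 2) of 0-based (ky, kz) lines.
#' @return complex array (nx, m, nCoils).
#' @export
encodeSegment <- function(vol, transform, coils, lines) {
  d <- dim(vol@data)
  if (!identical(d, dim(coils@maps)[1:3])) stop("grid mismatch")
  nc <- nCoils(coils)
  m <- nrow(lines)
  out <- array(0i, c(d[1L], m, nc))
  if (m == 0L) return(out)
  xt <- applyRigid(vol, transform)@data
  cols <- .lineCols(lines, d[2L])
  for (c_ in seq_len(nc)) {
    k <- fft3c(coils@maps[, , , c_] * xt)
    out[, , c_] <- matrix(k, d[1L], d[2L] * d[3L])[, cols, drop = FALSE]
  }
  out
}

#' Adjoint of the segment encoding
#'
#' Applies A^H = C_theta^H S^H F^-1 M^H: zero-fills the segment samples to
#' the full grid, inverse-FFTs per coil, combines with the conjugate coil
#' maps, and applies the exact transpose of the trilinear resampling.
#'
#' @param samples complex array (nx, m, nCoils) as from [encodeSegment()].
#' @param transform the segment's [RigidTransform-class].
#' @param coils a [CoilMaps-class].
#' @param lines integer matrix (m x 2) of 0-based (ky, kz) lines.
#' @param dims target grid (nx, ny, nz); defaults to the coil grid.
#' @param spacing voxel spacing of the target volume.
#' @return a complex [MRVolume-class].
#' @export
adjointSegment <- function(samples, transform, coils, lines,
                           dims = dim(coils@maps)[1:3],
                           spacing = coils@spacing) {
  if (nrow(lines) != dim(samples)[2L]) stop("mask/sample mismatch")
  nc <- nCoils(coils)
  acc <- array(0i, dims)
  cols <- .lineCols(lines, dims[2L])
  for (c_ in seq_len(nc)) {
    km <- matrix(0i, dims[1L], dims[2L] * dims[3L])
    km[, cols] <- samples[, , c_]
    acc <- acc + Conj(coils@maps[, , , c_]) * ifft3c(array(km, dims))
  }
  applyRigid(mrVolume(acc, spacing), transform, adjoint = TRUE)
}

#' Simulate a motion-corrupted multicoil acquisition
#'
#' For each shot, encodes the shot's phase-encode lines from the volume
#' transformed by the shot's motion state (motion is constant within a
#' shot), optionally adds i.i.d. complex Gaussian noise (std per real/imag
#' component), and assembles the samples per segment. Shots sharing a state
#' are encoded together, so the cost scales with the number of distinct
#' states.
#'
#' @param vol the still image ([MRVolume-class]).
#' @param traj a [MotionTrajectory-class] covering all shots.
#' @param scheme the [SamplingScheme-class].
#' @param coils a [CoilMaps-class].
#' @param noiseStd per-component std of the added complex noise (default 0).
#' @param seed integer seed for the noise realization.
#' @return a [SegmentedKSpace-class].
#' @export
simulateAcquisition <- function(vol, traj, scheme, coils, noiseStd = 0,
                                seed = 1L) {
  if (length(traj@assignment) != scheme@nShots)
    stop("incomplete trajectory: it must cover all shots of the scheme")
  d <- dim(vol@data)
  nc <- nCoils(coils)
  tfe <- scheme@tfeFactor
  shotData <- vector("list", scheme@nShots)
  for (st in unique(traj@assignment)) {
    shots <- which(traj@assignment == st)
    lines <- do.call(rbind, scheme@order[shots])
    enc <- encodeSegment(vol, traj@states[[st]], coils, lines)
    for (i in seq_along(shots)) {
      idx <- ((i - 1L) * tfe + 1L):(i * tfe)
      shotData[[shots[i]]] <- enc[, idx, , drop = FALSE]
    }
  }
  sps <- scheme@shotsPerSegment
  segs <- lapply(seq_len(nSegments(scheme)), function(s) {
    blocks <- shotData[((s - 1L) * sps + 1L):(s * sps)]
    out <- array(0i, c(d[1L], sps * tfe, nc))
    for (i in seq_along(blocks))
      out[, ((i - 1L) * tfe + 1L):(i * tfe), ] <- blocks[[i]]
    out
  })
  if (noiseStd > 0) {
    segs <- withSeed(seed, lapply(segs, function(sg) {
      sg + array(complex(real = rnorm(length(sg), 0, noiseStd),
                         imaginary = rnorm(length(sg), 0, noiseStd)),
                 dim(sg))
    }))
  }
  new("SegmentedKSpace", data = segs, lines = segmentLines(scheme),
      scheme = scheme, noiseStd = noiseStd)
}

#' Regroup segmented k-space at different segment size
#'
#' Splits each segment back into shots and regroups them under a new
#' `shotsPerSegment`, so a single simulated acquisition can be analysed at
#' several temporal resolutions.
#'
#' @param ks a [SegmentedKSpace-class].
#' @param shotsPerSegment new grouping (must divide the shot count).
#' @return a [SegmentedKSpace-class].
#' @export
regroupKSpace <- function(ks, shotsPerSegment) {
  scheme <- regroupScheme(ks@scheme, shotsPerSegment)
  tfe <- ks@scheme@tfeFactor
  oldSps <- ks@scheme@shotsPerSegment
  shotData <- vector("list", scheme@nShots)
  for (s in seq_along(ks@data)) {
    for (i in seq_len(oldSps)) {
      shot <- (s - 1L) * oldSps + i
      idx <- ((i - 1L) * tfe + 1L):(i * tfe)
      shotData[[shot]] <- ks@data[[s]][, idx, , drop = FALSE]
    }
  }
  d1 <- dim(ks@data[[1L]])[1L]
  nc <- dim(ks@data[[1L]])[3L]
  sps <- scheme@shotsPerSegment
  segs <- lapply(seq_len(nSegments(scheme)), function(s) {
    blocks <- shotData[((s - 1L) * sps + 1L):(s * sps)]
    out <- array(0i, c(d1, sps * tfe, nc))
    for (i in seq_along(blocks))
      out[, ((i - 1L) * tfe + 1L):(i * tfe), ] <- blocks[[i]]
    out
  })
  new("SegmentedKSpace", data = segs, lines = segmentLines(scheme),
      scheme = scheme, noiseStd = ks@noiseStd)
}
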