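#' Volume NIfTI I/O
#'
#' Writes a volume as NIfTI (magnitude for complex data) with its voxel
#' spacing, and reads one back as an [MRVolume-class].
#'
#' @param vol an [MRVolume-class].
#' @param path file path (`.nii` / `.nii.gz`).
#' @return `writeVolume` returns `path` invisibly; `readVolume` an
#'   [MRVolume-class].
#' @export
writeVolume <- function(vol, path) {
  dat <- if (is.complex(vol@data)) Mod(vol@data) else vol@data
  img <- RNifti::asNifti(dat, reference = NULL)
  RNifti::pixdim(img) <- vol@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) sp <- c(1, 1, 1)
  mrVolume(array(as.numeric(img), dim(img)[1:3]), sp)
}

#' Logical mask NIfTI I/O
#'
#' @param mask logical 3D array.
#' @param path file path.
#' @return `writeMask` returns `path` invisibly; `readMask` a logical array.
#' @export
writeMask <- function(mask, path) {
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(mask), dim(mask))),
                     path)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) > 0.5, dim(img)[1:3])
}

#' Sampling-scheme JSON I/O
#'
#' Serializes a [SamplingScheme-class] as JSON with 0-based (ky, kz)
#' ordered line lists per shot.
#'
#' @param scheme a [SamplingScheme-class].
#' @param path file path.
#' @return `writeScheme` returns `path` invisibly; `readScheme` a
#'   [SamplingScheme-class].
#' @export
writeScheme <- function(scheme, path) {
  obj <- list(ny = scheme@ny, nz = scheme@nz, tfe_factor = scheme@tfeFactor,
              n_shots = scheme@nShots,
              shots_per_segment = scheme@shotsPerSegment,
              seed = scheme@seed,
              order = lapply(scheme@order, function(m) unname(as.matrix(m))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeScheme
#' @export
readScheme <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  order <- if (is.array(obj$order) && length(dim(obj$order)) == 3L) {
    # equal-length shots simplify to one (nShots, tfe, 2) array
    lapply(seq_len(dim(obj$order)[1L]), function(s) obj$order[s, , ])
  } else {
    obj$order
  }
  order <- lapply(order, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    dimnames(m) <- NULL
    m
  })
  new("SamplingScheme", ny = as.integer(obj$ny), nz = as.integer(obj$nz),
      tfeFactor = as.integer(obj$tfe_factor),
      nShots = as.integer(obj$n_shots),
      shotsPerSegment = as.integer(obj$shots_per_segment),
      seed = as.integer(obj$seed), order = order)
}

#' Trajectory JSON I/O
#'
#' Serializes a [MotionTrajectory-class] as JSON, recording the rotation
#' convention (extrinsic x->y->z about the volume centre, degrees;
#' translation in mm, applied after rotation).
#'
#' @param traj a [MotionTrajectory-class].
#' @param path file path.
#' @return `writeTrajectory` returns `path` invisibly; `readTrajectory` a
#'   [MotionTrajectory-class].
#' @export
writeTrajectory <- function(traj, path) {
  obj <- list(
    convention = "extrinsic-xyz-deg-about-centre,translation-mm-after-rotation",
    states = lapply(traj@states, function(s)
      list(t = s@translation, r = s@rotation)),
    assignment = traj@assignment)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  states <- if (is.data.frame(obj$states)) {
    lapply(seq_len(nrow(obj$states)), function(i)
      rigidTransform(unlist(obj$states$t[i]), unlist(obj$states$r[i])))
  } else {
    lapply(obj$states, function(s) rigidTransform(unlist(s$t), unlist(s$r)))
  }
  motionTrajectory(states, as.integer(obj$assignment))
}

#' Segmented k-space / coil-map serialization
#'
#' Stores segmented k-space (or coil maps) losslessly via R's native
#' serialization: a list with the complex per-segment arrays, line lists
#' and scheme (respectively the complex 4D map array and spacing).
#'
#' @param ks a [SegmentedKSpace-class].
#' @param coils a [CoilMaps-class].
#' @param path file path (`.rds`).
#' @return the write functions return `path` invisibly; the readers return
#'   the corresponding object.
#' @export
writeKSpace <- function(ks, path) { saveRDS(ks, path); invisible(path) }

#' @rdname writeKSpace
#' @export
readKSpace <- function(path) readRDS(path)

#' @rdname writeKSpace
#' @export
writeCoilMaps <- function(coils, path) { saveRDS(coils, path); invisible(path) }

#' @rdname writeKSpace
#' @export
readCoilMaps <- function(path) readRDS(path)
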