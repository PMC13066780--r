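#' Rigid transform (6 parameters)
#'
#' A rigid-body transform parameterized by a translation in millimetres and
#' extrinsic Euler rotations in degrees about the volume centre, applied in
#' x, then y, then z order (rotation before translation). Angles are kept in
#' the canonical range (-180, 180].
#'
#' @slot translation numeric(3), millimetres.
#' @slot rotation numeric(3), degrees.
#' @export
setClass("RigidTransform",
  representation(translation = "numeric", rotation = "numeric"),
  prototype(translation = c(0, 0, 0), rotation = c(0, 0, 0)),
  validity = function(object) {
    if (length(object@translation) != 3L || length(object@rotation) != 3L)
      return("translation and rotation must each have length 3")
    if (!all(is.finite(object@translation)) || !all(is.finite(object@rotation)))
      return("transform parameters must be finite")
    if (any(object@rotation <= -180 - 1e-9) || any(object@rotation > 180 + 1e-9))
      return("rotation angles must lie in (-180, 180]")
    TRUE
  }
)

#' Motion trajectory
#'
#' An ordered list of per-state rigid transforms plus an assignment of
#' acquisition shots to motion states. Shots belonging to one state are
#' contiguous in acquisition order (motion is piecewise constant in time).
#'
#' @slot states list of [RigidTransform-class] objects.
#' @slot assignment integer vector, one state index per shot.
#' @export
setClass("MotionTrajectory",
  representation(states = "list", assignment = "integer"),
  validity = function(object) {
    if (!all(vapply(object@states, is, logical(1), "RigidTransform")))
      return("all states must be RigidTransform objects")
    n <- length(object@states)
    a <- object@assignment
    if (length(a) < 1L) return("assignment must cover at least one shot")
    if (any(a < 1L) || any(a > n)) return("assignment indices out of range")
    # contiguity: a state's shots form one run
    if (any(duplicated(a[c(TRUE, diff(a) != 0L)])))
      return("shots of one motion state must be contiguous in acquisition order")
    TRUE
  }
)

#' 3D image volume
#'
#' A 3D complex or real array with voxel spacing in millimetres. Voxel
#' (i, j, k) (1-based) sits at position ((i,j,k) - 1) * spacing; the rotation
#' centre and the FFT DC index are both at 0-based index floor(dim/2).
#'
#' @slot data 3D array (double or complex).
#' @slot spacing numeric(3), mm per voxel.
#' @export
setClass("MRVolume",
  representation(data = "array", spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L) return("data must be a 3D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive values")
    if (anyNA(object@data)) return("data must not contain NA")
    TRUE
  }
)

#' Complex coil-sensitivity maps
#'
#' Per-coil complex sensitivity volumes on a common grid, RSS-normalized so
#' that the squared magnitudes sum to one at every voxel with support.
#'
#' @slot maps 4D complex array (nx, ny, nz, nCoils).
#' @slot spacing numeric(3), mm per voxel.
#' @export
setClass("CoilMaps",
  representation(maps = "array", spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@maps)) != 4L) return("maps must be a 4D array")
    if (!is.complex(object@maps)) return("maps must be complex")
    TRUE
  }
)

#' Random-checkered sampling scheme
#'
#' Ordered lists of phase-encode (ky, kz) lines per shot over the ny-by-nz
#' phase-encode plane, with shots grouped into segments (the unit of motion
#' estimation). Indices are 0-based; the readout axis is fully sampled and
#' not represented.
#'
#' @slot ny,nz integer grid size of the phase-encode plane.
#' @slot tfeFactor integer, k-space lines per shot.
#' @slot nShots integer shot count.
#' @slot shotsPerSegment integer, shots grouped per motion state.
#' @slot seed integer seed used to generate the ordering.
#' @slot order list of integer matrices (tfeFactor x 2), 0-based (ky, kz).
#' @export
setClass("SamplingScheme",
  representation(ny = "integer", nz = "integer", tfeFactor = "integer",
                 nShots = "integer", shotsPerSegment = "integer",
                 seed = "integer", order = "list"),
  validity = function(object) {
    if (length(object@order) != object@nShots)
      return("order must hold one matrix per shot")
    all_lines <- do.call(rbind, object@order)
    if (any(all_lines[, 1L] < 0L) || any(all_lines[, 1L] >= object@ny) ||
        any(all_lines[, 2L] < 0L) || any(all_lines[, 2L] >= object@nz))
      return("sampled locations out of the phase-encode plane")
    for (m in object@order) {
      if (nrow(m) != object@tfeFactor)
        return("each shot must contain exactly tfeFactor locations")
    }
    key <- all_lines[, 1L] + object@ny * all_lines[, 2L]
    if (anyDuplicated(key)) return("a location is sampled more than once")
    if (object@nShots * object@tfeFactor > object@ny * object@nz)
      return("capacity exceeded: nShots * tfeFactor > ny * nz")
    if (object@nShots %% object@shotsPerSegment != 0L)
      return("nShots must be divisible by shotsPerSegment")
    TRUE
  }
)

#' Segmented multicoil k-space
#'
#' Per-segment complex k-space samples, each segment holding an array of
#' dimension (nx, nLines, nCoils) whose columns follow the acquisition order
#' of the segment's shots, plus the generating sampling scheme.
#'
#' @slot data list of complex arrays (nx, nLines, nCoils).
#' @slot lines list of integer matrices (nLines x 2), 0-based (ky, kz).
#' @slot scheme the [SamplingScheme-class].
#' @slot noiseStd numeric, per-component std of the added complex noise.
#' @export
setClass("SegmentedKSpace",
  representation(data = "list", lines = "list", scheme = "SamplingScheme",
                 noiseStd = "numeric"),
  validity = function(object) {
    if (length(object@data) != length(object@lines))
      return("data and lines must have the same length")
    ref <- segmentLines(object@scheme)
    if (length(ref) != length(object@lines))
      return("segment count does not match the scheme")
    for (i in seq_along(ref)) {
      if (!identical(dim(object@lines[[i]]), dim(ref[[i]])) ||
          any(object@lines[[i]] != ref[[i]]))
        return("segment line sets must match the scheme's masks exactly")
      if (dim(object@data[[i]])[2L] != nrow(object@lines[[i]]))
        return("segment data width must match its line count")
    }
    TRUE
  }
)

#' Per-segment reconstructions
#'
#' One magnitude volume per k-space segment, all on a common grid, as
#' produced by [reconstructSegments()].
#'
#' @slot volumes list of [MRVolume-class] magnitude volumes.
#' @slot method character tag of the reconstructor used.
#' @export
setClass("SegmentReconstruction",
  representation(volumes = "list", method = "character"),
  validity = function(object) {
    if (!all(vapply(object@volumes, is, logical(1), "MRVolume")))
      return("volumes must be MRVolume objects")
    dims <- lapply(object@volumes, function(v) dim(v@data))
    if (length(unique(dims)) > 1L) return("all volumes must share one grid")
    TRUE
  }
)

#' Groupwise registration result
#'
#' One rigid transform per segment, the final template, and the per-outer-
#' iteration objective trace (one row per template/transform update).
#'
#' @slot transforms list of [RigidTransform-class], one per segment.
#' @slot template [MRVolume-class] common template.
#' @slot trace data.frame with columns repeat_, level, outer, objective.
#' @slot settings list echoing the registration settings.
#' @export
setClass("GroupwiseResult",
  representation(transforms = "list", template = "MRVolume",
                 trace = "data.frame", settings = "list"),
  validity = function(object) {
    ok <- vapply(object@transforms, function(tr)
      all(is.finite(tr@translation)) && all(is.finite(tr@rotation)), logical(1))
    if (!all(ok)) return("transforms must be finite")
    TRUE
  }
)
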