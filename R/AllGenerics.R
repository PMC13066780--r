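#' @title Accessors
#' @description Small accessor generics for the package's S4 containers.
#' @param object an S4 object from this package.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("translation", function(object) standardGeneric("translation"))
#' @rdname accessors
#' @export
setGeneric("rotation", function(object) standardGeneric("rotation"))
#' @rdname accessors
#' @export
setGeneric("motionStates", function(object) standardGeneric("motionStates"))
#' @rdname accessors
#' @export
setGeneric("shotAssignment", function(object) standardGeneric("shotAssignment"))
#' @rdname accessors
#' @export
setGeneric("volumeData", function(object) standardGeneric("volumeData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("coilArray", function(object) standardGeneric("coilArray"))
#' @rdname accessors
#' @export
setGeneric("nCoils", function(object) standardGeneric("nCoils"))
#' @rdname accessors
#' @export
setGeneric("nShots", function(object) standardGeneric("nShots"))
#' @rdname accessors
#' @export
setGeneric("nSegments", function(object) standardGeneric("nSegments"))
#' @rdname accessors
#' @export
setGeneric("shotOrder", function(object) standardGeneric("shotOrder"))
#' @rdname accessors
#' @export
setGeneric("segmentData", function(object) standardGeneric("segmentData"))
#' @rdname accessors
#' @export
setGeneric("segmentVolumes", function(object) standardGeneric("segmentVolumes"))
#' @rdname accessors
#' @export
setGeneric("segmentTransforms", function(object) standardGeneric("segmentTransforms"))

setMethod("translation", "RigidTransform", function(object) object@translation)
setMethod("rotation", "RigidTransform", function(object) object@rotation)
setMethod("motionStates", "MotionTrajectory", function(object) object@states)
setMethod("shotAssignment", "MotionTrajectory", function(object) object@assignment)
setMethod("volumeData", "MRVolume", function(object) object@data)
setMethod("voxelSpacing", "MRVolume", function(object) object@spacing)
setMethod("coilArray", "CoilMaps", function(object) object@maps)
setMethod("nCoils", "CoilMaps", function(object) dim(object@maps)[4L])
setMethod("nShots", "SamplingScheme", function(object) object@nShots)
setMethod("nSegments", "SamplingScheme",
          function(object) object@nShots %/% object@shotsPerSegment)
setMethod("nSegments", "SegmentedKSpace", function(object) length(object@data))
setMethod("nSegments", "SegmentReconstruction", function(object) length(object@volumes))
setMethod("shotOrder", "SamplingScheme", function(object) object@order)
setMethod("segmentData", "SegmentedKSpace", function(object) object@data)
setMethod("segmentVolumes", "SegmentReconstruction", function(object) object@volumes)
setMethod("segmentTransforms", "GroupwiseResult", function(object) object@transforms)

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: t = (%.3f, %.3f, %.3f) mm, r = (%.3f, %.3f, %.3f) deg\n",
              object@translation[1], object@translation[2], object@translation[3],
              object@rotation[1], object@rotation[2], object@rotation[3]))
})

setMethod("show", "MotionTrajectory", function(object) {
  cat(sprintf("MotionTrajectory: %d states over %d shots\n",
              length(object@states), length(object@assignment)))
})

setMethod("show", "MRVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("MRVolume: %d x %d x %d (%s), spacing %.3g/%.3g/%.3g mm\n",
              d[1], d[2], d[3],
              if (is.complex(object@data)) "complex" else "real",
              object@spacing[1], object@spacing[2], object@spacing[3]))
})

setMethod("show", "CoilMaps", function(object) {
  d <- dim(object@maps)
  cat(sprintf("CoilMaps: %d coils on %d x %d x %d grid (RSS-normalized)\n",
              d[4], d[1], d[2], d[3]))
})

setMethod("show", "SamplingScheme", function(object) {
  cat(sprintf(paste0("SamplingScheme: %d x %d plane, %d shots x %d lines, ",
                     "%d shots/segment (%d segments), seed %d\n"),
              object@ny, object@nz, object@nShots, object@tfeFactor,
              object@shotsPerSegment, nSegments(object), object@seed))
})

setMethod("show", "SegmentedKSpace", function(object) {
  d <- dim(object@data[[1L]])
  cat(sprintf("SegmentedKSpace: %d segments, %d x %d x %d (kx, lines, coils) each\n",
              length(object@data), d[1], d[2], d[3]))
})

setMethod("show", "SegmentReconstruction", function(object) {
  cat(sprintf("SegmentReconstruction: %d segment volumes (method: %s)\n",
              length(object@volumes), object@method))
})

setMethod("show", "GroupwiseResult", function(object) {
  cat(sprintf("GroupwiseResult: %d transforms, final objective %.6g\n",
              length(object@transforms),
              if (nrow(object@trace)) object@trace$objective[nrow(object@trace)] else NA))
})
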