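#' Create a rigid transform
#'
#' @param translation numeric(3) translation in mm.
#' @param rotation numeric(3) rotation in degrees about the volume centre,
#'   extrinsic axes applied in x, then y, then z order (rotation before
#'   translation). Angles are wrapped to the canonical range (-180, 180].
#' @return a [RigidTransform-class] object.
#' @examples
#' rigidTransform(c(2, 0, 0), c(0, 0, 10))
#' @export
rigidTransform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0)) {
  new("RigidTransform",
      translation = as.numeric(translation),
      rotation = .wrapDeg(as.numeric(rotation)))
}

#' @rdname rigidTransform
#' @export
identityTransform <- function() rigidTransform()

# wrap angles to (-180, 180]
.wrapDeg <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

#' Rotation matrix of a rigid transform
#'
#' Returns the 3x3 rotation matrix R = Rz Ry Rx for the transform's Euler
#' angles (extrinsic x -> y -> z convention).
#'
#' @param transform a [RigidTransform-class].
#' @return 3x3 numeric matrix.
#' @export
rotationMatrix <- function(transform) {
  r <- transform@rotation * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# Euler angles (deg, extrinsic x->y->z) from a rotation matrix.
# M = Rz Ry Rx so M[3,1] = -sin(ry).
.eulerFromMatrix <- function(M) {
  sy <- -.clamp(M[3, 1], -1, 1)
  if (abs(sy) < 1 - 1e-10) {
    ry <- asin(sy)
    rx <- atan2(M[3, 2], M[3, 3])
    rz <- atan2(M[2, 1], M[1, 1])
  } else if (sy > 0) {        # ry = +90 deg, gimbal lock: fix rx = 0
    ry <- pi / 2
    rx <- 0
    rz <- atan2(-M[1, 2], M[1, 3])
  } else {                    # ry = -90 deg
    ry <- -pi / 2
    rx <- 0
    rz <- atan2(-M[1, 2], -M[1, 3])
  }
  c(rx, ry, rz) * 180 / pi
}

# build a transform from a rotation matrix + translation vector
.fromMatrix <- function(M, t) rigidTransform(t, .eulerFromMatrix(M))

#' Compose two rigid transforms
#'
#' `composeTransforms(a, b)` returns the transform that applies `b` first
#' and then `a`. Composition is associative with [identityTransform()] as
#' the neutral element; both rotations act about the same volume centre, so
#' the group is closed.
#'
#' @param a,b [RigidTransform-class] objects.
#' @return a [RigidTransform-class].
#' @export
composeTransforms <- function(a, b) {
  Ra <- rotationMatrix(a)
  Rb <- rotationMatrix(b)
  .fromMatrix(Ra %*% Rb, a@translation + as.numeric(Ra %*% b@translation))
}

#' Invert a rigid transform
#'
#' @param transform a [RigidTransform-class].
#' @return the inverse transform: `composeTransforms(transform,
#'   invertTransform(transform))` is the identity.
#' @export
invertTransform <- function(transform) {
  Rt <- t(rotationMatrix(transform))
  .fromMatrix(Rt, -as.numeric(Rt %*% transform@translation))
}

#' Distance between two rigid transforms
#'
#' Computes the relative transform `compose(invert(b), a)` and returns the
#' Euclidean norm of its translation (mm) and the geodesic angle of its
#' rotation part (degrees), i.e. `acos((trace(R_rel) - 1) / 2)`.
#'
#' @param a,b [RigidTransform-class] objects.
#' @return named numeric: `trans_mm`, `rot_deg`.
#' @export
transformDistance <- function(a, b) {
  Rrel <- t(rotationMatrix(b)) %*% rotationMatrix(a)
  trel <- t(rotationMatrix(b)) %*% (a@translation - b@translation)
  c(trans_mm = sqrt(sum(trel^2)),
    rot_deg = acos(.clamp((sum(diag(Rrel)) - 1) / 2, -1, 1)) * 180 / pi)
}

# Frechet mean of a list of transforms: arithmetic mean translation, chordal
# mean rotation (average matrices, project onto SO(3) by SVD).
.meanTransform <- function(transforms) {
  tm <- rowMeans(vapply(transforms, function(x) x@translation, numeric(3)))
  Rm <- Reduce(`+`, lapply(transforms, rotationMatrix)) / length(transforms)
  sv <- svd(Rm)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) {
    u <- sv$u; u[, 3] <- -u[, 3]
    R <- u %*% t(sv$v)
  }
  .fromMatrix(R, tm)
}
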