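#' Construct an MRVolume
#'
#' @param data 3D numeric or complex array.
#' @param spacing voxel spacing in mm (scalar or length 3).
#' @return an [MRVolume-class].
#' @export
mrVolume <- function(data, spacing = 1) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("MRVolume", data = data, spacing = as.numeric(spacing))
}

# centred coordinate arrays (0-based index minus floor(n/2)), one per axis
.coordArrays <- function(n) {
  c0 <- floor(n / 2)
  x <- (0:(n - 1)) - c0
  list(x = array(x, c(n, n, n)),
       y = array(rep(x, each = n), c(n, n, n)),
       z = array(rep(x, each = n * n), c(n, n, n)))
}

#' Deterministic brain-like phantom
#'
#' Builds an n-cubed head phantom from nested ellipsoids (scalp/skull shell,
#' brain, ventricles, an off-centre asymmetric frontal structure and a neck
#' column in the lowest slices) plus at least 20 small seeded ellipsoidal
#' lesions of 1-4 voxel extent that give registration-relevant texture.
#' Intensities are real, in [0, 1], with zero background; the phantom is
#' deliberately asymmetric so rigid registration is identifiable. A pure
#' function of `(n, seed)`.
#'
#' @param n grid size per axis (>= 16).
#' @param seed integer seed for lesion placement.
#' @param spacing voxel spacing in mm (default 1, so mm == voxel).
#' @return a real [MRVolume-class].
#' @export
makePhantom <- function(n, seed = 1L, spacing = 1) {
  if (n < 16) stop("n must be at least 16")
  co <- .coordArrays(n)
  h <- n / 2
  ell <- function(ox, oy, oz, a, b, c_) {
    ((co$x - ox) / a)^2 + ((co$y - oy) / b)^2 + ((co$z - oz) / c_)^2 <= 1
  }
  img <- array(0, c(n, n, n))
  # scalp/skull shell and brain, head centred slightly superior
  zc <- 0.12 * h
  img[ell(0, 0, zc, 0.78 * h, 0.92 * h, 0.72 * h)] <- 0.9
  img[ell(0, 0, zc, 0.70 * h, 0.84 * h, 0.64 * h)] <- 0.5
  # neck column occupying the inferior slices
  neck <- (co$x^2 + (co$y - 0.15 * h)^2 <= (0.32 * h)^2) & (co$z < -0.45 * h)
  img[neck] <- 0.4
  # ventricles (paired, darker) and an asymmetric frontal structure
  img[ell(-0.16 * h, 0.05 * h, zc + 0.08 * h, 0.10 * h, 0.22 * h, 0.10 * h)] <- 0.15
  img[ell(0.16 * h, 0.05 * h, zc + 0.08 * h, 0.10 * h, 0.22 * h, 0.10 * h)] <- 0.15
  img[ell(0.28 * h, -0.45 * h, zc, 0.18 * h, 0.16 * h, 0.20 * h)] <- 0.75
  # cerebellum-like inferior-posterior blob
  img[ell(0, 0.45 * h, zc - 0.38 * h, 0.30 * h, 0.22 * h, 0.18 * h)] <- 0.65
  # seeded lesions: small bright/dark ellipsoids inside the brain
  withSeed(seed, {
    nLesions <- 24L
    placed <- 0L
    while (placed < nLesions) {
      ox <- runif(1, -0.5, 0.5) * h
      oy <- runif(1, -0.6, 0.6) * h
      oz <- zc + runif(1, -0.45, 0.45) * h
      if ((ox / (0.70 * h))^2 + (oy / (0.84 * h))^2 +
          ((oz - zc) / (0.64 * h))^2 > 0.8) next
      r <- runif(3, 0.8, 2.2)       # semi-axes in voxels: 1-4 voxel extent
      val <- runif(1, 0.25, 1)
      img[ell(ox, oy, oz, r[1], r[2], r[3])] <- val
      placed <- placed + 1L
    }
  })
  mrVolume(.clamp(img, 0, 1), spacing)
}

#' Smooth complex coil-sensitivity maps
#'
#' Places `nCoils` Gaussian-lobe receive profiles on a ring around the
#' volume (alternating superior/inferior offsets), gives each a smooth
#' seeded linear phase ramp, and RSS-normalizes so the squared magnitudes
#' sum to one at every voxel. A pure function of `(n, nCoils, seed)`.
#'
#' @param n grid size per axis.
#' @param nCoils number of coils (>= 1).
#' @param seed integer seed (small jitter of lobe centres and phase ramps).
#' @param spacing voxel spacing in mm.
#' @return a [CoilMaps-class].
#' @export
makeCoilMaps <- function(n, nCoils, seed = 1L, spacing = 1) {
  stopifnot(nCoils >= 1)
  co <- .coordArrays(n)
  h <- n / 2
  maps <- array(0i, c(n, n, n, nCoils))
  withSeed(seed, {
    for (c_ in seq_len(nCoils)) {
      ang <- 2 * pi * (c_ - 1) / nCoils + runif(1, -0.1, 0.1)
      zoff <- (if (c_ %% 2 == 0) 0.3 else -0.3) * h + runif(1, -0.1, 0.1) * h
      cx <- 1.1 * h * cos(ang)
      cy <- 1.1 * h * sin(ang)
      sig <- 0.8 * h
      mag <- exp(-((co$x - cx)^2 + (co$y - cy)^2 + (co$z - zoff)^2) /
                   (2 * sig^2))
      ramp <- runif(3, -0.5, 0.5) * pi / n
      ph <- ramp[1] * co$x + ramp[2] * co$y + ramp[3] * co$z +
        runif(1, -pi, pi)
      maps[, , , c_] <- mag * exp(1i * ph)
    }
  })
  rssNormalize(new("CoilMaps", maps = maps,
                   spacing = rep(as.numeric(spacing), length.out = 3L)))
}

#' Root-sum-of-squares normalization of coil maps
#'
#' Scales the maps so that `sum_c |S_c(v)|^2 = 1` wherever any coil has
#' support.
#'
#' @param coils a [CoilMaps-class].
#' @return the normalized [CoilMaps-class].
#' @export
rssNormalize <- function(coils) {
  m <- coils@maps
  rss <- sqrt(apply(Mod(m)^2, 1:3, sum))
  rss[rss == 0] <- 1
  for (c_ in seq_len(dim(m)[4L])) m[, , , c_] <- m[, , , c_] / rss
  initialize(coils, maps = m)
}

#' SVD compression of coil maps
#'
#' Projects the coil dimension onto the top-k left singular vectors of the
#' coil-by-voxel matrix, then re-applies RSS normalization.
#'
#' @param coils a [CoilMaps-class].
#' @param k number of virtual coils to keep (`k <= nCoils`).
#' @return a [CoilMaps-class] with `k` coils.
#' @export
svdCompressCoils <- function(coils, k) {
  nc <- nCoils(coils)
  if (k < 1 || k > nc) stop("k must lie in [1, nCoils]")
  d <- dim(coils@maps)
  C <- t(matrix(coils@maps, prod(d[1:3]), nc))   # coils x voxels
  sv <- svd(C, nu = k, nv = 0)
  comp <- Conj(t(sv$u[, seq_len(k), drop = FALSE])) %*% C
  maps <- array(t(comp), c(d[1:3], k))
  rssNormalize(new("CoilMaps", maps = maps, spacing = coils@spacing))
}

#' Registration mask of a volume
#'
#' `full` is the support of the volume; `head_only` additionally removes
#' the lowest 20% of axial slices (the neck region, prone to nonrigid
#' motion).
#'
#' @param vol an [MRVolume-class].
#' @param mode "full" or "head_only".
#' @param threshold support threshold on the magnitude.
#' @return a logical 3D array.
#' @export
makeRegistrationMask <- function(vol, mode = c("full", "head_only"),
                                 threshold = 1e-8) {
  mode <- match.arg(mode)
  mask <- Mod(vol@data) > threshold
  if (mode == "head_only") {
    nz <- dim(mask)[3L]
    mask[, , seq_len(floor(0.2 * nz))] <- FALSE
  }
  mask
}
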