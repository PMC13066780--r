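#' 3D structural similarity index (SSIM)
#'
#' Mean local SSIM with 3D Gaussian windows (sigma 1.5 voxels, 11-voxel
#' window) and the standard constants K1 = 0.01, K2 = 0.03, population
#' (not sample) local moments. The data range defaults to the maximum of
#' the reference `b` (SSIM is range-sensitive, so the convention is fixed
#' here). A border of half the window width is excluded from the mean; an
#' optional mask restricts the mean further.
#'
#' @param a,b real magnitude [MRVolume-class] (or 3D arrays) on one grid;
#'   `b` is the reference.
#' @param dataRange intensity range; default `max(b)`.
#' @param sigma Gaussian window std in voxels.
#' @param mask optional logical array.
#' @return scalar SSIM in [-1, 1].
#' @export
ssim3d <- function(a, b, dataRange = NULL, sigma = 1.5, mask = NULL) {
  x <- if (is(a, "MRVolume")) Mod(a@data) else Mod(a)
  y <- if (is(b, "MRVolume")) Mod(b@data) else Mod(b)
  if (!identical(dim(x), dim(y))) stop("grid mismatch")
  if (is.null(dataRange)) dataRange <- max(y)
  rad <- as.integer(round(3.5 * sigma))     # 11-voxel window at sigma 1.5
  w <- exp(-(((-rad):rad)^2) / (2 * sigma^2))
  w <- w / sum(w)
  f <- function(z) .sepConv3(z, w)
  C1 <- (0.01 * dataRange)^2
  C2 <- (0.03 * dataRange)^2
  ux <- f(x); uy <- f(y)
  vx <- f(x * x) - ux * ux
  vy <- f(y * y) - uy * uy
  vxy <- f(x * y) - ux * uy
  ssimMap <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  d <- dim(x)
  keep <- array(FALSE, d)
  keep[(rad + 1L):(d[1L] - rad), (rad + 1L):(d[2L] - rad),
       (rad + 1L):(d[3L] - rad)] <- TRUE
  if (!is.null(mask)) keep <- keep & mask
  mean(ssimMap[keep])
}

# separable 3D convolution with a symmetric 1D kernel, zero-padded edges
# (the uncropped border is excluded by the SSIM mean)
.sepConv3 <- function(arr, w) {
  d <- dim(arr)
  rad <- (length(w) - 1L) %/% 2L
  kmat <- function(n) {
    K <- matrix(0, n, n)
    for (off in (-rad):rad) {
      i <- seq_len(n)
      j <- i + off
      ok <- j >= 1L & j <= n
      K[cbind(i[ok], j[ok])] <- K[cbind(i[ok], j[ok])] + w[off + rad + 1L]
    }
    K
  }
  x <- array(kmat(d[1L]) %*% matrix(arr, d[1L], d[2L] * d[3L]), d)
  x <- aperm(x, c(2L, 1L, 3L))
  x <- array(kmat(d[2L]) %*% matrix(x, d[2L], d[1L] * d[3L]), c(d[2L], d[1L], d[3L]))
  x <- aperm(x, c(2L, 1L, 3L))
  x <- aperm(x, c(3L, 2L, 1L))
  x <- array(kmat(d[3L]) %*% matrix(x, d[3L], d[2L] * d[1L]), c(d[3L], d[2L], d[1L]))
  aperm(x, c(3L, 2L, 1L))
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(max(b)^2 / MSE)` with `b` the reference; identical inputs give
#' `Inf`.
#'
#' @param a,b [MRVolume-class] or arrays on one grid; `b` is the reference.
#' @param mask optional logical array restricting the MSE.
#' @return PSNR in dB.
#' @export
psnr <- function(a, b, mask = NULL) {
  x <- if (is(a, "MRVolume")) Mod(a@data) else Mod(a)
  y <- if (is(b, "MRVolume")) Mod(b@data) else Mod(b)
  if (!identical(dim(x), dim(y))) stop("grid mismatch")
  if (max(y) == 0) stop("zero reference")
  e <- (x - y)^2
  mse <- if (is.null(mask)) mean(e) else mean(e[mask])
  if (mse == 0) return(Inf)
  10 * log10(max(y)^2 / mse)
}

#' Normalized mean squared error
#'
#' `||a - b||^2 / ||b||^2` with `b` the reference.
#'
#' @inheritParams psnr
#' @return NMSE (>= 0).
#' @export
nmse <- function(a, b, mask = NULL) {
  x <- if (is(a, "MRVolume")) Mod(a@data) else Mod(a)
  y <- if (is(b, "MRVolume")) Mod(b@data) else Mod(b)
  if (!identical(dim(x), dim(y))) stop("grid mismatch")
  if (!is.null(mask)) {
    x <- x[mask]; y <- y[mask]
  }
  if (sum(y^2) == 0) stop("zero reference")
  sum((x - y)^2) / sum(y^2)
}

#' Gauge-invariant trajectory error
#'
#' Removes the global rigid offset between the estimated and ground-truth
#' trajectories ([removeGlobalOffset()]), expands both to per-shot states
#' (so a 16- or 64-state estimate can be compared against a per-shot ground
#' truth), and averages [transformDistance()] over shots.
#'
#' @param est,gt [MotionTrajectory-class] objects over the same shot count.
#' @return named numeric: `mean_mm`, `mean_deg`.
#' @export
trajectoryError <- function(est, gt) {
  if (length(est@assignment) != length(gt@assignment))
    stop("incompatible trajectories: different shot counts")
  aligned <- removeGlobalOffset(est, gt)
  es <- shotTransforms(aligned)
  gs <- shotTransforms(gt)
  d <- vapply(seq_along(es), function(s)
    transformDistance(es[[s]], gs[[s]]), numeric(2))
  c(mean_mm = mean(d[1, ]), mean_deg = mean(d[2, ]))
}
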