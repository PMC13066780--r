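#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded generators are pure
#' functions of their arguments without clobbering the caller's stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# circular shift of an n-d array: y[j] = x[j - sh] (per dimension, modular)
.circShift <- function(x, sh) {
  d <- dim(x)
  idx <- lapply(seq_along(d), function(i) ((seq_len(d[i]) - 1 - sh[i]) %% d[i]) + 1L)
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Centred orthonormal 3D Fourier transform
#'
#' DC is at grid index `floor(n/2) + 1` along each axis (the convention used
#' by all sampling masks in the package); the transform is unitary so
#' Parseval's identity holds exactly.
#'
#' @param x complex (or numeric) 3D array.
#' @return complex 3D array of the same dimensions.
#' @export
fft3c <- function(x) {
  s <- floor(dim(x) / 2)
  .circShift(stats::fft(.circShift(x, -s)), s) / sqrt(length(x))
}

#' @rdname fft3c
#' @export
ifft3c <- function(x) {
  s <- floor(dim(x) / 2)
  .circShift(stats::fft(.circShift(x, -s), inverse = TRUE), s) / sqrt(length(x))
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# map (ky, kz) 0-based line indices to columns of an (nx, ny*nz) k-space matrix
.lineCols <- function(lines, ny) lines[, 1L] + 1L + lines[, 2L] * ny
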