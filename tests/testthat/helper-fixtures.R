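# Small deterministic fixtures shared across test files. Everything is
# generated in code; sizes are kept small so the full suite runs quickly.

fixPhantom <- function(n = 32L, seed = 1L) makePhantom(n, seed)

fixCoils <- function(n = 32L, nc = 4L, seed = 2L) makeCoilMaps(n, nc, seed)

fixScheme <- function(n = 32L, nShots = 8L,
                      tfe = as.integer(n * n / nShots),
                      sps = 1L, seed = 3L) {
  generateDisorderScheme(n, n, nShots, tfe, sps, seed)
}

randTransform <- function(seed, tScale = 3, rScale = 25) {
  withr::with_seed(seed,
    rigidTransform(runif(3, -tScale, tScale), runif(3, -rScale, rScale)))
}

# complex random volume
randComplexVolume <- function(n, seed) {
  withr::with_seed(seed,
    mrVolume(array(complex(real = rnorm(n^3), imaginary = rnorm(n^3)),
                   c(n, n, n))))
}
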