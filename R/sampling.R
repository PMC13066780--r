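# Tile grid used by the random-checkered order: factor tfeFactor as ay * az
# with ay/az closest to ny/nz (log-ratio) among the grids whose smallest
# tile can hold one location for every shot; tiles are contiguous
# rectangles with remainder rows/columns absorbed by edge tiles.
.tileGrid <- function(ny, nz, tfeFactor, nShots) {
  divs <- which(tfeFactor %% seq_len(tfeFactor) == 0)
  best <- NULL
  bestScore <- Inf
  fits <- FALSE
  for (ay in divs) {
    az <- tfeFactor %/% ay
    if (ay > ny || az > nz) next
    fits <- TRUE
    if ((ny %/% ay) * (nz %/% az) < nShots) next   # smallest tile too small
    score <- abs(log((ay / az) / (ny / nz)))
    if (score < bestScore - 1e-12) {
      bestScore <- score
      best <- c(ay, az)
    }
  }
  if (is.null(best)) {
    if (!fits)
      stop(sprintf("tiling impossible: tfeFactor %d has no divisor grid fitting %d x %d",
                   tfeFactor, ny, nz))
    stop(sprintf("capacity exceeded: no %d-tile grid over %d x %d holds %d shots per tile",
                 tfeFactor, ny, nz, nShots))
  }
  best
}

#' Generate a random-checkered sampling scheme
#'
#' Builds a distributed-incoherent ordering of the ny-by-nz phase-encode
#' plane: the plane is tiled into `tfeFactor` near-equal contiguous
#' rectangles and every shot samples exactly one location per tile, so each
#' shot (and hence each segment) spans low and high spatial frequencies.
#' Within each tile the assignment of locations to shots is a seeded random
#' draw, and within each shot the tile visiting order is a seeded random
#' permutation. The construction is a pure function of its arguments.
#'
#' @param ny,nz size of the phase-encode plane.
#' @param nShots number of shots.
#' @param tfeFactor lines acquired per shot (the turbo factor).
#' @param shotsPerSegment shots grouped per motion state.
#' @param seed integer seed.
#' @return a [SamplingScheme-class].
#' @examples
#' sc <- generateDisorderScheme(8, 8, nShots = 4, tfeFactor = 16, seed = 1)
#' @export
generateDisorderScheme <- function(ny, nz, nShots, tfeFactor,
                                   shotsPerSegment = 1L, seed = 1L) {
  ny <- as.integer(ny); nz <- as.integer(nz)
  nShots <- as.integer(nShots); tfeFactor <- as.integer(tfeFactor)
  if (nShots * tfeFactor > ny * nz)
    stop(sprintf("capacity exceeded: %d shots x %d lines > %d x %d plane",
                 nShots, tfeFactor, ny, nz))
  if (nShots %% shotsPerSegment != 0)
    stop("nShots must be divisible by shotsPerSegment")
  g <- .tileGrid(ny, nz, tfeFactor, nShots)
  ay <- g[1]; az <- g[2]
  yb <- floor((0:ay) * ny / ay)   # 0-based tile boundaries
  zb <- floor((0:az) * nz / az)
  # cells of each tile (0-based linear key ky + ny * kz)
  tiles <- vector("list", tfeFactor)
  ti <- 0L
  for (tz in seq_len(az)) {
    for (ty in seq_len(ay)) {
      ti <- ti + 1L
      kys <- yb[ty]:(yb[ty + 1L] - 1L)
      kzs <- zb[tz]:(zb[tz + 1L] - 1L)
      tiles[[ti]] <- as.vector(outer(kys, kzs * ny, `+`))
    }
  }
  small <- min(lengths(tiles))
  if (nShots > small)
    stop(sprintf("capacity exceeded: smallest tile of the %d x %d grid holds %d < %d shots",
                 ay, az, small, nShots))
  withSeed(seed, {
    # per tile: which cell each shot gets (seeded draw without replacement)
    cellOf <- vapply(tiles, function(cells)
      cells[sample.int(length(cells), nShots)], integer(nShots))
    if (nShots == 1L) cellOf <- matrix(cellOf, nrow = 1L)
    order <- lapply(seq_len(nShots), function(s) {
      visit <- sample.int(tfeFactor)
      keys <- cellOf[s, visit]
      cbind(keys %% ny, keys %/% ny)
    })
    new("SamplingScheme", ny = ny, nz = nz, tfeFactor = tfeFactor,
        nShots = nShots, shotsPerSegment = as.integer(shotsPerSegment),
        seed = as.integer(seed),
        order = lapply(order, function(m) {
          storage.mode(m) <- "integer"; dimnames(m) <- NULL; m
        }))
  })
}

#' Per-segment line lists of a scheme
#'
#' @param scheme a [SamplingScheme-class].
#' @return list of integer matrices (lines x 2, 0-based (ky, kz)), one per
#'   segment, concatenating the segment's shots in acquisition order.
#' @export
segmentLines <- function(scheme) {
  sps <- scheme@shotsPerSegment
  lapply(seq_len(nSegments(scheme)), function(s) {
    do.call(rbind, scheme@order[((s - 1L) * sps + 1L):(s * sps)])
  })
}

#' Binary segment masks of a scheme
#'
#' @param scheme a [SamplingScheme-class].
#' @return list of logical ny-by-nz matrices, one per segment; masks are
#'   pairwise disjoint and their union is the full sampled set.
#' @export
segmentMasks <- function(scheme) {
  lapply(segmentLines(scheme), function(ln) {
    m <- matrix(FALSE, scheme@ny, scheme@nz)
    m[cbind(ln[, 1L] + 1L, ln[, 2L] + 1L)] <- TRUE
    m
  })
}

#' Accelerate a scheme by discarding shots
#'
#' Retrospective undersampling: retains `round(nShots / R)` shots (rounded
#' to the nearest multiple of `shotsPerSegment` so whole segments survive),
#' selected by a seeded uniform draw without replacement; retained shots
#' keep their original within-shot ordering and relative order.
#'
#' @param scheme a [SamplingScheme-class].
#' @param R acceleration factor (>= 1); `R = 1` returns the scheme
#'   unchanged.
#' @param seed integer seed for the shot draw.
#' @return a [SamplingScheme-class] with the retained shots.
#' @export
accelerateByShotDiscarding <- function(scheme, R, seed = 1L) {
  stopifnot(R >= 1)
  if (R == 1) return(scheme)
  sps <- scheme@shotsPerSegment
  keep <- round(scheme@nShots / R)
  keep <- as.integer(round(keep / sps) * sps)
  if (keep < sps)
    stop("R too large: fewer than one segment of shots would remain")
  sel <- withSeed(seed, sort(sample.int(scheme@nShots, keep)))
  new("SamplingScheme", ny = scheme@ny, nz = scheme@nz,
      tfeFactor = scheme@tfeFactor, nShots = keep,
      shotsPerSegment = sps, seed = scheme@seed,
      order = scheme@order[sel])
}

#' Change the segment grouping of a scheme
#'
#' @param scheme a [SamplingScheme-class].
#' @param shotsPerSegment new grouping (must divide the shot count).
#' @return a [SamplingScheme-class] differing only in the grouping.
#' @export
regroupScheme <- function(scheme, shotsPerSegment) {
  if (scheme@nShots %% shotsPerSegment != 0)
    stop("shotsPerSegment must divide nShots")
  initialize(scheme, shotsPerSegment = as.integer(shotsPerSegment))
}
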