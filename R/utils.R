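# Internal helpers shared across modules.

# 6-connected component labelling of a logical 3D array. Returns an integer
# array of component ids (0 = background). Vectorized frontier BFS; intended
# for ROI-scale masks, not whole scans.
labelComponents3D <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxy <- d[1] * d[2]
  remaining <- which(mask)
  comp <- 0L
  while (length(remaining)) {
    comp <- comp + 1L
    frontier <- remaining[1]
    lab[frontier] <- comp
    while (length(frontier)) {
      ai <- arrayInd(frontier, d)
      cand <- rbind(
        cbind(ai[, 1] + 1L, ai[, 2], ai[, 3]),
        cbind(ai[, 1] - 1L, ai[, 2], ai[, 3]),
        cbind(ai[, 1], ai[, 2] + 1L, ai[, 3]),
        cbind(ai[, 1], ai[, 2] - 1L, ai[, 3]),
        cbind(ai[, 1], ai[, 2], ai[, 3] + 1L),
        cbind(ai[, 1], ai[, 2], ai[, 3] - 1L)
      )
      ok <- cand[, 1] >= 1L & cand[, 1] <= d[1] &
            cand[, 2] >= 1L & cand[, 2] <= d[2] &
            cand[, 3] >= 1L & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      lin <- unique(cand[, 1] + (cand[, 2] - 1L) * d[1] + (cand[, 3] - 1L) * nxy)
      lin <- lin[mask[lin] & lab[lin] == 0L]
      lab[lin] <- comp
      frontier <- lin
    }
    remaining <- remaining[lab[remaining] == 0L]
  }
  lab
}

# Unweighted centroid of a logical array, 1-based voxel coordinates.
maskCentroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  colMeans(idx)
}

# Nearest voxel index to a fractional coordinate; exact ties (.5) resolve to
# the lower index (inferior / posterior / left side).
nearestIndexTieLow <- function(x) as.integer(ceiling(x - 0.5))

# Clip values into [lo, hi]; returns list(values, nClipped).
clipRange <- function(x, lo = 0, hi = 100) {
  bad <- is.finite(x) & (x < lo | x > hi)
  x[is.finite(x) & x < lo] <- lo
  x[is.finite(x) & x > hi] <- hi
  list(values = x, nClipped = sum(bad))
}
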