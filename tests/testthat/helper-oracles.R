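# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately written from first principles (explicit
# enumeration, all-pairs distances) rather than through the package's own
# code paths.

# Physical coordinates (mm) of all TRUE voxels of a logical array.
voxel_coords_mm <- function(occ, spacing, origin = c(0, 0, 0)) {
  idx <- which(occ, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, spacing, `*`), 2, origin, `+`)
}

# Boundary voxels by explicit 6-neighbour inspection (volume edge counts as
# unoccupied).
brute_boundary <- function(occ) {
  d <- dim(occ)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!occ[i, j, k]) next
    nb <- c(
      if (i > 1) occ[i - 1, j, k] else FALSE,
      if (i < d[1]) occ[i + 1, j, k] else FALSE,
      if (j > 1) occ[i, j - 1, k] else FALSE,
      if (j < d[2]) occ[i, j + 1, k] else FALSE,
      if (k > 1) occ[i, j, k - 1] else FALSE,
      if (k < d[3]) occ[i, j, k + 1] else FALSE)
    out[i, j, k] <- !all(nb)
  }
  out
}

# All-pairs directed/symmetric HD95 between two masks: for each boundary
# voxel of A the distance to the nearest boundary voxel of B, 95th
# percentile with linear interpolation (quantile type 7), max of the two
# directions.
brute_hd95 <- function(a_occ, b_occ, spacing, probs = 0.95) {
  pa <- voxel_coords_mm(brute_boundary(a_occ), spacing)
  pb <- voxel_coords_mm(brute_boundary(b_occ), spacing)
  dmat <- sqrt(outer(pa[, 1], pb[, 1], `-`)^2 +
                 outer(pa[, 2], pb[, 2], `-`)^2 +
                 outer(pa[, 3], pb[, 3], `-`)^2)
  ab <- quantile(apply(dmat, 1, min), probs, type = 7, names = FALSE)
  ba <- quantile(apply(dmat, 2, min), probs, type = 7, names = FALSE)
  max(ab, ba)
}

# Random connected-ish blob: union of a few random ellipsoids; never empty.
random_blob <- function(grid, n_ell = 2) {
  d <- grid$shape
  occ <- array(FALSE, d)
  ext <- (d - 1) * grid$spacing_mm
  for (e in seq_len(n_ell)) {
    ctr <- runif(3, 0.25, 0.75) * ext
    semi <- runif(3, 0.15, 0.35) * ext
    x <- (seq_len(d[1]) - 1) * grid$spacing_mm[1]
    y <- (seq_len(d[2]) - 1) * grid$spacing_mm[2]
    z <- (seq_len(d[3]) - 1) * grid$spacing_mm[3]
    occ <- occ | (outer(outer(((x - ctr[1]) / semi[1])^2,
                              ((y - ctr[2]) / semi[2])^2, `+`),
                        ((z - ctr[3]) / semi[3])^2, `+`) <= 1)
  }
  if (!any(occ)) occ[ceiling(d[1] / 2), ceiling(d[2] / 2), ceiling(d[3] / 2)] <- TRUE
  occ
}

# Small test grid for phantom-based tests: coarse but large enough in mm.
small_phantom_grid <- function() voxel_grid(c(64L, 64L, 48L), c(2, 2, 5))

cube_mask <- function(grid, from, to, label = "cube") {
  occ <- array(FALSE, dim = grid$shape)
  occ[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  structure_mask(occ, grid, label)
}
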