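# Independent brute-force oracles and small fixture builders shared by the
# unit tests. The oracles deliberately avoid the package's vectorized code
# paths: plain loops over voxels/points only.

small_grid <- function(n = 20L) voxel_grid(rep(n, 3L))

# density map from explicit voxel->count pairs (0-based voxel indices)
map_from_counts <- function(vox, counts, grid = small_grid()) {
  arr <- array(0L, dim = grid$shape)
  for (i in seq_len(nrow(vox))) {
    arr[vox[i, 1L] + 1L, vox[i, 2L] + 1L, vox[i, 3L] + 1L] <- counts[i]
  }
  structure(list(counts = arr, grid = grid), class = "density_map")
}

random_density_map <- function(grid = small_grid(), n_vox = 30L) {
  dimg <- grid$shape
  vox <- unique(cbind(sample(0:(dimg[1L] - 1L), n_vox, TRUE),
                      sample(0:(dimg[2L] - 1L), n_vox, TRUE),
                      sample(0:(dimg[3L] - 1L), n_vox, TRUE)))
  map_from_counts(vox, sample(1:5, nrow(vox), TRUE), grid)
}

# voxel-by-voxel loop evaluation of the weighted Dice formula
oracle_wdice <- function(dA, dB) {
  num <- 0; den <- 0
  for (i in seq_along(dA$counts)) {
    a <- dA$counts[i]; b <- dB$counts[i]
    if (a > 0 && b > 0) num <- num + a + b
    den <- den + a + b
  }
  num / den
}

# brute-force nearest-voxel-centre search for bundle adjacency
oracle_ba <- function(dA, dB) {
  centres <- function(d) {
    w <- which(d$counts > 0L, arr.ind = TRUE) - 1L
    w + 0.5  # identity affines only in these fixtures
  }
  cA <- centres(dA); cB <- centres(dB)
  kA <- apply(cA, 1L, paste, collapse = ","); kB <- apply(cB, 1L, paste, collapse = ",")
  mindist <- function(p, set) {
    best <- Inf
    for (j in seq_len(nrow(set))) best <- min(best, sqrt(sum((p - set[j, ])^2)))
    best
  }
  term <- function(from_c, from_k, to_c, to_k) {
    only <- !(from_k %in% to_k)
    if (!any(only)) return(0)
    mean(vapply(which(only), function(i) mindist(from_c[i, ], to_c),
                numeric(1L)))
  }
  0.5 * (term(cA, kA, cB, kB) + term(cB, kB, cA, kA))
}

# straight-line streamline along x at a given (y, z), in world mm
straight_streamline <- function(x0, x1, y, z, n = 2L) {
  cbind(seq(x0, x1, length.out = n), rep(y, n), rep(z, n))
}

# brute-force MDF distance between two resampled streamlines
oracle_mdf <- function(s1, s2, n_points = 20L) {
  r1 <- resample_streamline(s1, n_points = n_points)
  r2 <- resample_streamline(s2, n_points = n_points)
  direct <- mean(sqrt(rowSums((r1 - r2)^2)))
  flipped <- mean(sqrt(rowSums((r1 - r2[n_points:1L, ])^2)))
  min(direct, flipped)
}
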