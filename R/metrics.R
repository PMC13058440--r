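# Bundle geometry and comparison metrics: arc lengths, length filtering,
# streamline density maps, outlier rejection, weighted Dice, bundle adjacency.

#' Arc length of a streamline
#'
#' Sum of Euclidean distances between consecutive points, in mm.
#'
#' @param s Numeric matrix with 3 columns (>= 2 rows).
#' @return Length in mm.
#' @examples
#' streamline_length(rbind(c(0, 0, 0), c(3, 4, 0)))  # 5
#' @export
streamline_length <- function(s) {
  s <- as.matrix(s)
  if (nrow(s) < 2L) stop("a streamline needs >= 2 points", call. = FALSE)
  sum(sqrt(rowSums(diff(s)^2)))
}

#' Per-streamline length statistics of a bundle
#'
#' @param b A [bundle()].
#' @return A list with `lengths` (mm, one per streamline), `min`, `max`,
#'   `mean`, `sd` (sample SD, `NA` for < 2 streamlines).
#' @export
bundle_lengths <- function(b) {
  lens <- vapply(b$streamlines, streamline_length, numeric(1L))
  list(lengths = lens,
       min = if (length(lens)) min(lens) else NA_real_,
       max = if (length(lens)) max(lens) else NA_real_,
       mean = if (length(lens)) mean(lens) else NA_real_,
       sd = if (length(lens) >= 2L) stats::sd(lens) else NA_real_)
}

#' Filter a bundle by maximum streamline length
#'
#' Retains exactly the streamlines with arc length <= `max_mm`, preserving
#' order. Mirrors the per-tract maximum-length restriction used to keep
#' reconstructions short-range.
#'
#' @param b A [bundle()].
#' @param max_mm Positive length threshold in mm.
#' @return The filtered bundle (possibly empty).
#' @export
filter_by_max_length <- function(b, max_mm) {
  if (!is.numeric(max_mm) || length(max_mm) != 1L || max_mm <= 0)
    stop("max_mm must be a single positive number", call. = FALSE)
  keep <- vapply(b$streamlines, streamline_length, numeric(1L)) <= max_mm
  b$streamlines <- b$streamlines[keep]
  b
}

#' Resample a streamline at (approximately) equidistant arc-length steps
#'
#' @param s Numeric matrix with 3 columns.
#' @param step Target spacing in mm (points are spaced exactly
#'   `length/ceiling(length/step)` <= `step` apart); ignored if `n_points`
#'   is given.
#' @param n_points Resample to exactly this many equidistant points instead.
#' @return A matrix of resampled points (first and last points preserved).
#' @export
resample_streamline <- function(s, step = 0.2, n_points = NULL) {
  s <- as.matrix(s)
  seg <- sqrt(rowSums(diff(s)^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  if (is.null(n_points)) {
    n_points <- max(2L, as.integer(ceiling(total / step)) + 1L)
  }
  if (n_points < 2L) stop("n_points must be >= 2", call. = FALSE)
  target <- seq(0, total, length.out = n_points)
  out <- cbind(stats::approx(arc, s[, 1L], xout = target, ties = "ordered")$y,
               stats::approx(arc, s[, 2L], xout = target, ties = "ordered")$y,
               stats::approx(arc, s[, 3L], xout = target, ties = "ordered")$y)
  out
}

#' Streamline density map of a bundle
#'
#' Counts, for each voxel of the grid, the number of streamlines whose path
#' visits the voxel; each streamline contributes at most 1 per voxel.
#' Visitation is determined by resampling each streamline at steps of at most
#' `step` mm (default 0.2 mm, a fifth of the default 1 mm voxel) and
#' collecting unique voxel indices. Points falling outside the grid are
#' ignored with a warning.
#'
#' @param b A [bundle()].
#' @param grid A [voxel_grid()]; defaults to the bundle's own grid.
#' @param step Resampling step in mm.
#' @return An object of class `density_map`: list with `counts` (3D integer
#'   array) and `grid`.
#' @export
density_map <- function(b, grid = b$grid, step = 0.2) {
  counts <- array(0L, dim = grid$shape)
  outside <- FALSE
  dimg <- grid$shape
  for (s in b$streamlines) {
    pts <- resample_streamline(s, step = step)
    vox <- floor(.world_to_voxel(pts, grid))
    ok <- vox[, 1L] >= 0 & vox[, 1L] < dimg[1L] &
          vox[, 2L] >= 0 & vox[, 2L] < dimg[2L] &
          vox[, 3L] >= 0 & vox[, 3L] < dimg[3L]
    if (!all(ok)) outside <- TRUE
    vox <- vox[ok, , drop = FALSE]
    if (nrow(vox) == 0L) next
    lin <- unique(1L + vox[, 1L] + dimg[1L] * (vox[, 2L] + dimg[2L] * vox[, 3L]))
    counts[lin] <- counts[lin] + 1L
  }
  if (outside)
    warning("streamline points outside the grid were ignored", call. = FALSE)
  structure(list(counts = counts, grid = grid), class = "density_map")
}

#' Support of a density map
#' @param d A [density_map()].
#' @return 0-based voxel index matrix (one row per voxel with count > 0).
#' @export
support_voxels <- function(d) {
  lin <- which(d$counts > 0L) - 1L
  dimg <- d$grid$shape
  cbind(lin %% dimg[1L],
        (lin %/% dimg[1L]) %% dimg[2L],
        lin %/% (dimg[1L] * dimg[2L]))
}

.check_same_grid <- function(dA, dB) {
  if (!all(dA$grid$shape == dB$grid$shape) ||
      max(abs(dA$grid$affine - dB$grid$affine)) > 1e-6)
    stop("density maps are defined on different grids", call. = FALSE)
}

#' Weighted Dice overlap of two density maps
#'
#' Density-weighted volumetric overlap, sensitive to the agreement of the
#' high-density cores of two bundles:
#' \deqn{wDice = \frac{\sum_{v \in S_A \cap S_B} (d_A[v] + d_B[v])}
#'                    {\sum_v d_A[v] + \sum_v d_B[v]}}
#' where \eqn{S_A, S_B} are the supports. Equals the plain Dice coefficient
#' when all counts are 1, is symmetric, and lies in [0, 1]: 1 for identical
#' non-empty maps, 0 for disjoint supports.
#'
#' @param dA,dB [density_map()]s on the same grid.
#' @param normalize Divide each map by its total count first (fractional
#'   densities). Default `FALSE` (raw counts).
#' @return wDice in `[0, 1]`.
#' @export
weighted_dice <- function(dA, dB, normalize = FALSE) {
  .check_same_grid(dA, dB)
  a <- as.numeric(dA$counts); b <- as.numeric(dB$counts)
  if (normalize) {
    if (sum(a) > 0) a <- a / sum(a)
    if (sum(b) > 0) b <- b / sum(b)
  }
  ta <- sum(a); tb <- sum(b)
  if (ta == 0 && tb == 0)
    stop("weighted Dice is undefined for two empty density maps", call. = FALSE)
  inter <- a > 0 & b > 0
  sum(a[inter] + b[inter]) / (ta + tb)
}

#' Bundle adjacency of two density maps
#'
#' Average distance (mm, between voxel centres) between the non-overlapping
#' portions of two bundle supports:
#' \deqn{BA = \tfrac12\Big[\mathrm{mean}_{v \in S_A \setminus S_B}
#'   \min_{u \in S_B} \|c_v - c_u\| +
#'   \mathrm{mean}_{v \in S_B \setminus S_A} \min_{u \in S_A} \|c_v - c_u\|\Big]}
#' If one set difference is empty its term is 0 (the half-weighting still
#' applies); identical supports give 0. A value of 3 mm means that where the
#' bundles differ, their volumes are on average 3 mm apart.
#'
#' @param dA,dB [density_map()]s on the same grid, both with non-empty
#'   support.
#' @return Bundle adjacency in mm.
#' @export
bundle_adjacency <- function(dA, dB) {
  .check_same_grid(dA, dB)
  sA <- support_voxels(dA); sB <- support_voxels(dB)
  if (nrow(sA) == 0L || nrow(sB) == 0L)
    stop("bundle adjacency requires non-empty supports", call. = FALSE)
  cA <- .voxel_to_world(sA + 0.5, dA$grid)
  cB <- .voxel_to_world(sB + 0.5, dB$grid)
  keyA <- do.call(paste, c(as.data.frame(sA), sep = ","))
  keyB <- do.call(paste, c(as.data.frame(sB), sep = ","))
  onlyA <- !(keyA %in% keyB)
  onlyB <- !(keyB %in% keyA)
  term <- function(from, to) {
    if (nrow(from) == 0L) return(0)
    mean(.min_dists(from, to))
  }
  0.5 * (term(cA[onlyA, , drop = FALSE], cB) +
         term(cB[onlyB, , drop = FALSE], cA))
}

# rowwise min Euclidean distance from each point in `from` to the set `to`,
# chunked to bound memory
.min_dists <- function(from, to, chunk = 512L) {
  n <- nrow(from)
  to_sq <- rowSums(to^2)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    f <- from[idx, , drop = FALSE]
    d2 <- outer(rowSums(f^2), to_sq, "+") - 2 * f %*% t(to)
    out[idx] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  out
}

#' Compare two bundles (weighted Dice, bundle adjacency, overlap)
#'
#' Convenience wrapper computing both comparison metrics from density maps.
#'
#' @param a,b [bundle()]s or [density_map()]s on a shared grid.
#' @param grid Grid used when `a`/`b` are bundles.
#' @return A data frame with columns `wdice`, `bundle_adjacency_mm`,
#'   `overlap_voxels`.
#' @export
compare_bundles <- function(a, b, grid = NULL) {
  dA <- if (inherits(a, "density_map")) a else
    density_map(a, grid = if (is.null(grid)) a$grid else grid)
  dB <- if (inherits(b, "density_map")) b else
    density_map(b, grid = if (is.null(grid)) b$grid else grid)
  .check_same_grid(dA, dB)
  data.frame(
    wdice = weighted_dice(dA, dB),
    bundle_adjacency_mm = bundle_adjacency(dA, dB),
    overlap_voxels = sum(dA$counts > 0L & dB$counts > 0L)
  )
}

# mean-direct-flip distance matrix between streamlines resampled to a common
# number of points
.mdf_matrix <- function(streamlines, n_points = 20L) {
  n <- length(streamlines)
  rs <- lapply(streamlines, resample_streamline, n_points = n_points)
  flat <- t(vapply(rs, function(m) as.numeric(m), numeric(3L * n_points)))
  flat_rev <- t(vapply(rs, function(m) as.numeric(m[n_points:1L, , drop = FALSE]),
                       numeric(3L * n_points)))
  ix <- seq_len(n_points); iy <- n_points + ix; iz <- 2L * n_points + ix
  mean_pt_dist <- function(ref, m) {
    rowMeans(sqrt(sweep(m[, ix, drop = FALSE], 2L, ref[ix], "-")^2 +
                  sweep(m[, iy, drop = FALSE], 2L, ref[iy], "-")^2 +
                  sweep(m[, iz, drop = FALSE], 2L, ref[iz], "-")^2))
  }
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d[i, ] <- pmin(mean_pt_dist(flat[i, ], flat),
                   mean_pt_dist(flat[i, ], flat_rev))
  }
  diag(d) <- 0
  d
}

#' Reject outlier streamlines from a bundle
#'
#' One-pass rejection on mean-direct-flip (MDF) distances: every streamline
#' is resampled to `n_points` equidistant points; the MDF distance between
#' two streamlines is the smaller of the direct and flipped mean point-wise
#' distances. A streamline is rejected iff its average MDF distance to all
#' other streamlines exceeds `mean + alpha * sd` of those per-streamline
#' averages.
#'
#' @param b A [bundle()] (>= 3 streamlines; smaller bundles are returned
#'   unchanged with a warning).
#' @param alpha Rejection threshold in SD units (default 2).
#' @param n_points Resampling resolution (default 20).
#' @return A list with `kept` and `rejected` bundles (a partition of the
#'   input, order preserved within each).
#' @export
reject_outliers <- function(b, alpha = 2, n_points = 20L) {
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  if (n_points < 2L) stop("n_points must be >= 2", call. = FALSE)
  n <- length(b$streamlines)
  empty <- b; empty$streamlines <- list()
  if (n < 3L) {
    warning("fewer than 3 streamlines; no outlier rejection performed",
            call. = FALSE)
    return(list(kept = b, rejected = empty))
  }
  d <- .mdf_matrix(b$streamlines, n_points = n_points)
  avg <- rowSums(d) / (n - 1L)
  thr <- mean(avg) + alpha * stats::sd(avg)
  rej <- avg > thr
  kept <- b; kept$streamlines <- b$streamlines[!rej]
  rejected <- b; rejected$streamlines <- b$streamlines[rej]
  list(kept = kept, rejected = rejected)
}
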