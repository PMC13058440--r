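test_that("streamline lengths match hand geometry and a loop oracle", {
  expect_equal(streamline_length(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  expect_equal(streamline_length(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))), 2)
  set.seed(3)
  s <- matrix(runif(30, 0, 10), 10L, 3L)
  oracle <- 0
  for (i in 1:9) oracle <- oracle + sqrt(sum((s[i + 1L, ] - s[i, ])^2))
  expect_equal(streamline_length(s), oracle)
  expect_error(streamline_length(matrix(1, 1L, 3L)), ">= 2 points")
})

test_that("filter_by_max_length retains exactly the short streamlines", {
  g <- small_grid()
  b <- bundle(list(straight_streamline(0, 10, 3.5, 3.5),   # 10 mm
                   straight_streamline(0, 15, 4.5, 3.5),   # 15 mm
                   straight_streamline(0, 19, 5.5, 3.5)),  # 19 mm
              grid = g)
  expect_equal(n_streamlines(filter_by_max_length(b, 16)), 2L)
  expect_equal(n_streamlines(filter_by_max_length(b, 1e9)), 3L)
  expect_equal(n_streamlines(filter_by_max_length(b, 5)), 0L)
  # order preserved
  kept <- filter_by_max_length(b, 16)
  expect_equal(kept$streamlines, b$streamlines[1:2])
  expect_error(filter_by_max_length(b, -1), "positive")
})

test_that("density_map counts visited voxels once per streamline", {
  g <- small_grid()
  s <- straight_streamline(0.5, 4.5, 0.5, 0.5)   # crosses voxels x = 0..4
  d <- density_map(bundle(list(s), grid = g))
  expect_equal(sum(d$counts > 0L), 5L)
  expect_true(all(d$counts[d$counts > 0L] == 1L))
  expect_equal(which(d$counts > 0L, arr.ind = TRUE)[, 1L], 1:5,
               ignore_attr = TRUE)

  d2 <- density_map(bundle(list(s, s), grid = g))
  expect_equal(sum(d2$counts > 0L), 5L)
  expect_true(all(d2$counts[d2$counts > 0L] == 2L))

  expect_true(all(density_map(bundle(list(), grid = g))$counts == 0L))
})

test_that("density_map is additive over concatenated bundles", {
  g <- small_grid()
  set.seed(8)
  mk <- function() resample_streamline(matrix(runif(9, 2, 18), 3L, 3L), 1)
  s1 <- lapply(1:4, function(i) mk()); s2 <- lapply(1:3, function(i) mk())
  d1 <- density_map(bundle(s1, grid = g))
  d2 <- density_map(bundle(s2, grid = g))
  d12 <- density_map(bundle(c(s1, s2), grid = g))
  expect_equal(d12$counts, d1$counts + d2$counts)
})

test_that("points outside the grid are ignored with a warning", {
  g <- small_grid()
  s <- straight_streamline(-5, 5, 0.5, 0.5)
  expect_warning(d <- density_map(bundle(list(s), grid = g)), "outside")
  expect_equal(sum(d$counts > 0L), 6L)  # x voxels 0..5
})

test_that("weighted_dice: identity, disjoint, hand case, oracle, symmetry", {
  g <- small_grid()
  dA <- map_from_counts(rbind(c(1, 1, 1), c(2, 1, 1)), c(2L, 1L), g)
  expect_equal(weighted_dice(dA, dA), 1)

  dDisj <- map_from_counts(rbind(c(9, 9, 9)), 4L, g)
  expect_equal(weighted_dice(dA, dDisj), 0)

  # dA = {v1:2, v2:1}, dB = {v1:1, v3:3} -> (2+1)/(3+4) = 3/7
  dB <- map_from_counts(rbind(c(1, 1, 1), c(5, 5, 5)), c(1L, 3L), g)
  expect_equal(weighted_dice(dA, dB), 3 / 7)

  set.seed(21)
  for (rep in 1:200) {
    m1 <- random_density_map(); m2 <- random_density_map()
    got <- weighted_dice(m1, m2)
    expect_equal(got, oracle_wdice(m1, m2))
    expect_equal(got, weighted_dice(m2, m1))
    expect_gte(got, 0); expect_lte(got, 1)
  }

  empty <- map_from_counts(matrix(0L, 0L, 3L), integer(0L), g)
  expect_error(weighted_dice(empty, empty), "empty")
  expect_error(weighted_dice(dA, random_density_map(small_grid(15L))),
               "different grids")
})

test_that("weighted_dice equals plain Dice when all counts are 1", {
  set.seed(4)
  for (rep in 1:20) {
    m1 <- random_density_map(); m2 <- random_density_map()
    m1$counts[m1$counts > 0L] <- 1L
    m2$counts[m2$counts > 0L] <- 1L
    inter <- sum(m1$counts > 0L & m2$counts > 0L)
    dice <- 2 * inter / (sum(m1$counts) + sum(m2$counts))
    expect_equal(weighted_dice(m1, m2), dice)
  }
})

test_that("bundle_adjacency: identical, parallel lines, subset, oracle", {
  g <- small_grid()
  dA <- map_from_counts(cbind(0:9, 0L, 0L), rep(1L, 10L), g)
  expect_equal(bundle_adjacency(dA, dA), 0)

  # two parallel single-voxel lines 3 voxels apart on a 1 mm grid -> 3 mm
  dB <- map_from_counts(cbind(0:9, 3L, 0L), rep(1L, 10L), g)
  expect_equal(bundle_adjacency(dA, dB), 3)
  expect_equal(bundle_adjacency(dB, dA), 3)

  # strict subset: BA = half the mean distance from B \ A to A
  dSub <- map_from_counts(cbind(0:4, 0L, 0L), rep(1L, 5L), g)
  expect_equal(bundle_adjacency(dSub, dA), oracle_ba(dSub, dA))
  expect_equal(bundle_adjacency(dSub, dA), 0.5 * mean(1:5))

  set.seed(33)
  for (rep in 1:200) {
    m1 <- random_density_map(n_vox = 12L)
    m2 <- random_density_map(n_vox = 12L)
    got <- bundle_adjacency(m1, m2)
    expect_equal(got, oracle_ba(m1, m2))
    expect_equal(got, bundle_adjacency(m2, m1))
    expect_gte(got, 0)
  }

  empty <- map_from_counts(matrix(0L, 0L, 3L), integer(0L), g)
  expect_error(bundle_adjacency(dA, empty), "non-empty")
})

test_that("joint translation leaves wDice and bundle adjacency unchanged", {
  g <- small_grid(40L)
  set.seed(6)
  mk <- function() lapply(1:5, function(i)
    resample_streamline(matrix(runif(9, 5, 20), 3L, 3L), 1))
  b1 <- bundle(mk(), grid = g); b2 <- bundle(mk(), grid = g)
  tr <- diag(4); tr[1:3, 4L] <- c(4, 3, 7)  # integer shift: exact on the grid
  d1 <- density_map(b1); d2 <- density_map(b2)
  t1 <- density_map(apply_affine(b1, tr)); t2 <- density_map(apply_affine(b2, tr))
  expect_equal(weighted_dice(t1, t2), weighted_dice(d1, d2))
  expect_equal(bundle_adjacency(t1, t2), bundle_adjacency(d1, d2))
})

test_that("reject_outliers removes the far streamline and partitions input", {
  g <- small_grid(60L)
  set.seed(12)
  arcs <- lapply(1:10, function(i) {
    base <- .5 + cbind(5:25, 10 + 3 * sin(seq(0, pi, length.out = 21)), 10)
    base + matrix(rnorm(63, 0, 0.2), 21L, 3L)
  })
  far <- straight_streamline(5.5, 25.5, 40.5, 40.5, n = 21L)
  b <- bundle(c(arcs, list(far)), grid = g)
  res <- reject_outliers(b, alpha = 2)
  expect_equal(n_streamlines(res$rejected), 1L)
  expect_equal(res$rejected$streamlines[[1L]], far)
  expect_equal(n_streamlines(res$kept), 10L)
  # partition property: kept + rejected = input, disjoint
  expect_setequal(c(res$kept$streamlines, res$rejected$streamlines),
                  b$streamlines)

  same <- bundle(rep(list(arcs[[1L]]), 5L), grid = g)
  res2 <- reject_outliers(same)
  expect_equal(n_streamlines(res2$rejected), 0L)

  two <- bundle(arcs[1:2], grid = g)
  expect_warning(res3 <- reject_outliers(two), "fewer than 3")
  expect_equal(n_streamlines(res3$kept), 2L)
})

test_that("internal MDF distances agree with a brute-force oracle", {
  set.seed(14)
  streams <- lapply(1:6, function(i) matrix(runif(12, 0, 10), 4L, 3L))
  d <- tractconcord:::.mdf_matrix(streams, n_points = 15L)
  for (i in 1:6) for (j in 1:6) {
    if (i == j) next
    expect_equal(d[i, j], oracle_mdf(streams[[i]], streams[[j]], 15L))
  }
  expect_equal(d, t(d))
})

test_that("resample_streamline preserves endpoints and spacing", {
  s <- rbind(c(0, 0, 0), c(10, 0, 0))
  r <- resample_streamline(s, step = 1)
  expect_equal(r[1L, ], c(0, 0, 0))
  expect_equal(r[nrow(r), ], c(10, 0, 0))
  gaps <- sqrt(rowSums(diff(r)^2))
  expect_true(all(gaps <= 1 + 1e-9))
  expect_equal(nrow(resample_streamline(s, n_points = 7L)), 7L)
})
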