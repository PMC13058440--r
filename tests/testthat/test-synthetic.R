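test_that("u-fiber generation is deterministic and respects its spec", {
  sp <- bundle_spec(endpoints = rbind(c(20, 40, 40), c(50, 40, 40)),
                    arc_depth = 10, n_streamlines = 100L,
                    radial_jitter_sd = 1)
  b1 <- generate_u_bundle(sp, seed = 7L)
  b2 <- generate_u_bundle(sp, seed = 7L)
  expect_identical(b1$streamlines, b2$streamlines)
  expect_equal(n_streamlines(b1), 100L)
  lens <- bundle_lengths(b1)$lengths
  expect_true(all(lens >= sp$length_range[1L] & lens <= sp$length_range[2L]))
  # density support forms one connected component
  frac <- tractconcord:::.largest_component_fraction(
    support_voxels(density_map(b1)))
  expect_equal(frac, 1)
})

test_that("zero jitter reproduces the centreline exactly (wDice 1)", {
  sp <- bundle_spec(endpoints = rbind(c(20, 40, 40), c(50, 40, 40)),
                    n_streamlines = 5L, radial_jitter_sd = 0)
  b <- generate_u_bundle(sp, seed = 1L)
  for (i in 2:5) expect_equal(b$streamlines[[i]], b$streamlines[[1L]])
  b2 <- generate_u_bundle(sp, seed = 99L)  # regeneration, any seed
  expect_equal(weighted_dice(density_map(b), density_map(b2)), 1)
})

test_that("unsatisfiable length ranges are an error", {
  sp <- bundle_spec(endpoints = rbind(c(20, 40, 40), c(50, 40, 40)),
                    length_range = c(5, 20))  # chord alone is 30 mm
  expect_error(generate_u_bundle(sp, seed = 1L), "unsatisfiable")
})

test_that("spurious bundles are rougher than u-fibers and fail the scorer", {
  ep <- rbind(c(20, 40, 40), c(50, 40, 40))
  u <- generate_u_bundle(bundle_spec(endpoints = ep, n_streamlines = 30L),
                         seed = 3L)
  s <- generate_spurious_bundle(
    bundle_spec(endpoints = ep, n_streamlines = 30L, kind = "spurious"),
    seed = 3L)
  expect_gt(mean_turning_angle(s), mean_turning_angle(u))
  roi_a <- sphere_mask(default_grid(), ep[1L, ], 5)
  roi_b <- sphere_mask(default_grid(), ep[2L, ], 5)
  expect_equal(assess_plausibility(u, roi_a, roi_b)$value, "plausible")
  expect_equal(assess_plausibility(s, roi_a, roi_b)$value, "implausible")
  # determinism
  s2 <- generate_spurious_bundle(
    bundle_spec(endpoints = ep, n_streamlines = 30L, kind = "spurious"),
    seed = 3L)
  expect_identical(s$streamlines, s2$streamlines)
})

test_that("absent specs yield empty bundles", {
  sp <- bundle_spec(pair = c("8", "9"), kind = "absent")
  expect_equal(n_streamlines(generate_bundle(sp)), 0L)
  expect_equal(sp$n_streamlines, 0L)
})

test_that("cohort statuses follow the prevalence/implausible_rate model", {
  pairs <- enumerate_pairs()[1:4, ]
  all_p <- generate_cohort(cohort_spec(10L, pairs, prevalence = 1,
                                       implausible_rate = 0, seed = 2L))
  expect_true(all(all_p$ledger$status == "plausible"))
  none <- generate_cohort(cohort_spec(10L, pairs, prevalence = 0,
                                      implausible_rate = 0, seed = 2L))
  expect_true(all(none$ledger$status == "absent"))

  co <- generate_cohort(cohort_spec(200L, pairs[1L, , drop = FALSE],
                                    prevalence = 0.85, seed = 5L))
  f <- mean(co$ledger$status == "plausible")
  ci <- stats::binom.test(sum(co$ledger$status == "plausible"),
                          nrow(co$ledger))$conf.int
  expect_true(0.85 >= ci[1L] && 0.85 <= ci[2L])

  # reproducibility and ledger shape
  co2 <- generate_cohort(cohort_spec(200L, pairs[1L, , drop = FALSE],
                                     prevalence = 0.85, seed = 5L))
  expect_identical(co$ledger, co2$ledger)
  expect_equal(nrow(co$ledger), 200L)
})

test_that("cohorts with geometry write readable TRK files and a ledger", {
  pairs <- data.frame(area_a = "8", area_b = "9")
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_spec(2L, pairs, prevalence = 1, seed = 3L),
                        make_bundles = TRUE, out_dir = dir,
                        n_streamlines = 25L)
  f <- file.path(dir, "sub-001", "pair-8_9.trk")
  expect_true(file.exists(f))
  expect_equal(n_streamlines(read_trk(f)), 25L)
  expect_true(file.exists(file.path(dir, "ledger.csv")))
})

test_that("retest perturbations are seeded and ordered by design", {
  sp <- bundle_spec(endpoints = rbind(c(20, 40, 40), c(50, 40, 40)),
                    n_streamlines = 25L)
  b <- generate_u_bundle(sp, seed = 10L)
  r1 <- make_retest_pair(b, mode = "within", seed = 4L)
  r2 <- make_retest_pair(b, mode = "within", seed = 4L)
  expect_identical(r1$streamlines, r2$streamlines)

  zero <- retest_spec(within_jitter_sd = 1e-12)
  rz <- make_retest_pair(b, zero, mode = "within", seed = 1L)
  dz <- density_map(rz); db <- density_map(b)
  expect_equal(weighted_dice(db, dz), 1)
  expect_equal(bundle_adjacency(db, dz), 0)

  expect_error(make_retest_pair(bundle(list(), b$grid)), "empty")
  expect_error(retest_spec(within_jitter_sd = 3, between_jitter_sd = 2),
               "smaller")
})

test_that("within perturbations beat between perturbations on both metrics", {
  sp <- bundle_spec(endpoints = rbind(c(20, 40, 40), c(50, 40, 40)),
                    n_streamlines = 25L)
  b <- generate_u_bundle(sp, seed = 20L)
  db <- density_map(b)
  rs <- retest_spec()
  wd_w <- ba_w <- wd_b <- ba_b <- numeric(20L)
  for (k in 1:20) {
    dw <- density_map(make_retest_pair(b, rs, "within", seed = k))
    dbw <- density_map(make_retest_pair(b, rs, "between", seed = 1000L + k))
    wd_w[k] <- weighted_dice(db, dw); ba_w[k] <- bundle_adjacency(db, dw)
    wd_b[k] <- weighted_dice(db, dbw); ba_b[k] <- bundle_adjacency(db, dbw)
  }
  expect_gt(mean(wd_w), mean(wd_b))
  expect_lt(mean(ba_w), mean(ba_b))
})

test_that("degradation is monotone in jitter magnitude (Monte-Carlo)", {
  sp <- bundle_spec(endpoints = rbind(c(25, 40, 40), c(45, 40, 40)),
                    n_streamlines = 15L)
  b <- generate_u_bundle(sp, seed = 30L)
  db <- density_map(b)
  jitters <- c(0.25, 1, 4)
  wd <- ba <- numeric(3L)
  for (j in seq_along(jitters)) {
    rs <- retest_spec(within_jitter_sd = jitters[j],
                      between_jitter_sd = jitters[j] + 1e-9,
                      rigid_shift_sd = 0)
    wds <- bas <- numeric(20L)
    for (k in 1:20) {
      d <- density_map(make_retest_pair(b, rs, "within", seed = 31L * j + k))
      wds[k] <- weighted_dice(db, d); bas[k] <- bundle_adjacency(db, d)
    }
    wd[j] <- mean(wds); ba[j] <- mean(bas)
  }
  expect_true(all(diff(wd) < 0))
  expect_true(all(diff(ba) > 0))
})

test_that("synthetic area centres exist for all areas, in short-range reach", {
  ac <- area_centers()
  expect_setequal(ac$label, pfc_areas()$label)
  xyz <- as.matrix(ac[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  off <- d[upper.tri(d)]
  expect_true(all(off > 5 & off < 70))
  g <- default_grid()$shape
  expect_true(all(xyz > 5) && all(sweep(xyz, 2L, g, "<") == 1))
})
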