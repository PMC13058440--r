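# Synthetic bundle simulator: coherent U-shaped fiber bundles between two
# endpoint regions, spurious (implausible) bundles, absent bundles, cohorts
# with per-pair prevalences, and scan-rescan replicates. The simulator
# defines the statistical structure the downstream analysis assumes; it makes
# no attempt to emulate diffusion signal or a tracking algorithm.

# run expr with a private RNG stream; global RNG state is untouched
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Synthetic centroid coordinates for the 14 prefrontal areas
#'
#' Deterministic world-mm positions on the default 90 x 110 x 90 grid,
#' arranged so that every area pair is 10-60 mm apart (the short-range
#' regime). These are synthetic stand-ins, not atlas coordinates.
#'
#' @return A data frame with columns `label`, `x`, `y`, `z` (mm).
#' @export
area_centers <- function() {
  m <- rbind(
    "8"    = c(30, 55, 70),
    "9"    = c(35, 75, 65),
    "46"   = c(25, 75, 55),
    "9/46" = c(25, 60, 55),
    "44"   = c(20, 55, 40),
    "45"   = c(20, 68, 38),
    "47"   = c(25, 78, 30),
    "11"   = c(35, 80, 20),
    "13"   = c(40, 70, 18),
    "14"   = c(45, 72, 15),
    "10"   = c(35, 95, 40),
    "24"   = c(45, 65, 45),
    "25"   = c(45, 70, 28),
    "32"   = c(42, 78, 50)
  )
  data.frame(label = rownames(m), x = m[, 1L], y = m[, 2L], z = m[, 3L],
             row.names = NULL, stringsAsFactors = FALSE)
}

.center_of <- function(label) {
  ac <- area_centers()
  i <- match(label, ac$label)
  if (anyNA(i)) stop("no synthetic centre for area ", label, call. = FALSE)
  unname(as.matrix(ac[i, c("x", "y", "z")]))
}

#' Specification of one synthetic bundle
#'
#' @param pair Length-2 character vector of area labels (canonicalized), or
#'   `NULL` for a free bundle.
#' @param endpoints 2 x 3 matrix of world-mm endpoints; defaults to the
#'   [area_centers()] of `pair`.
#' @param arc_depth Depth (mm) of the U-arc: the Bezier control point is
#'   displaced this far perpendicular to the chord. Default 8.
#' @param n_streamlines Number of streamlines (default 100).
#' @param radial_jitter_sd SD (mm) of the smooth per-streamline offsets
#'   (default 1).
#' @param length_range Admissible arc-length interval in mm
#'   (default `c(5, 125)`, within the study's 38-125 mm per-tract maxima).
#' @param kind `"u_fiber"`, `"spurious"` or `"absent"`.
#' @return An object of class `bundle_spec`.
#' @export
bundle_spec <- function(pair = NULL, endpoints = NULL, arc_depth = 8,
                        n_streamlines = 100L, radial_jitter_sd = 1,
                        length_range = c(5, 125), kind = "u_fiber") {
  kind <- match.arg(kind, c("u_fiber", "spurious", "absent"))
  if (is.null(endpoints)) {
    if (is.null(pair)) stop("either pair or endpoints is required", call. = FALSE)
    endpoints <- .center_of(pair)
  }
  endpoints <- matrix(as.numeric(endpoints), 2L, 3L)
  if (n_streamlines < 0L) stop("n_streamlines must be >= 0", call. = FALSE)
  if (radial_jitter_sd < 0) stop("radial_jitter_sd must be >= 0", call. = FALSE)
  if (kind == "absent") n_streamlines <- 0L
  structure(list(pair = pair, endpoints = endpoints, arc_depth = arc_depth,
                 n_streamlines = as.integer(n_streamlines),
                 radial_jitter_sd = radial_jitter_sd,
                 length_range = length_range, kind = kind),
            class = "bundle_spec")
}

# unit vector perpendicular to v, deterministic choice
.perp_unit <- function(v) {
  ref <- c(0, 0, 1)
  if (abs(sum(v * ref)) / sqrt(sum(v^2)) > 0.9) ref <- c(0, 1, 0)
  p <- c(v[2L] * ref[3L] - v[3L] * ref[2L],
         v[3L] * ref[1L] - v[1L] * ref[3L],
         v[1L] * ref[2L] - v[2L] * ref[1L])
  p / sqrt(sum(p^2))
}

# quadratic Bezier through A, control C, B sampled at ~1 mm arc steps
.bezier_centerline <- function(a, b, arc_depth, step = 1) {
  mid <- (a + b) / 2
  ctrl <- mid + arc_depth * .perp_unit(b - a)
  tt <- seq(0, 1, length.out = 200L)
  curve <- outer((1 - tt)^2, a) + outer(2 * tt * (1 - tt), ctrl) +
           outer(tt^2, b)
  resample_streamline(curve, step = step)
}

# smooth correlated Gaussian offsets: N(0, sd) values at knots every
# `knot_spacing` mm, spline-interpolated to all sample points
.smooth_offsets <- function(n_pts, total_len, sd, knot_spacing = 8) {
  if (sd == 0) return(matrix(0, n_pts, 3L))
  n_knots <- max(3L, as.integer(ceiling(total_len / knot_spacing)) + 1L)
  kx <- seq(0, 1, length.out = n_knots)
  px <- seq(0, 1, length.out = n_pts)
  vapply(1:3, function(j) {
    stats::spline(kx, stats::rnorm(n_knots, 0, sd), xout = px)$y
  }, numeric(n_pts))
}

#' Generate a coherent U-shaped fiber bundle
#'
#' The centreline is a quadratic Bezier from one endpoint to the other with
#' its control point displaced `arc_depth` mm perpendicular to the chord;
#' each streamline is the centreline sampled at ~1 mm steps plus smooth
#' correlated Gaussian offsets (`radial_jitter_sd`). Streamlines whose arc
#' length falls outside `length_range` are redrawn. Deterministic for a fixed
#' seed.
#'
#' @param spec A [bundle_spec()] with `kind = "u_fiber"`.
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @param grid The [voxel_grid()] reference.
#' @return A [bundle()].
#' @export
generate_u_bundle <- function(spec, seed = NULL, grid = default_grid()) {
  if (spec$kind != "u_fiber") stop("spec$kind must be 'u_fiber'", call. = FALSE)
  center <- .bezier_centerline(spec$endpoints[1L, ], spec$endpoints[2L, ],
                               spec$arc_depth)
  clen <- streamline_length(center)
  if (clen < spec$length_range[1L] || clen > spec$length_range[2L])
    stop(sprintf(paste0("length_range [%g, %g] mm is unsatisfiable: the ",
                        "centreline between the endpoints is %.1f mm"),
                 spec$length_range[1L], spec$length_range[2L], clen),
         call. = FALSE)
  n_pts <- nrow(center)
  streams <- .with_seed(seed, {
    lapply(seq_len(spec$n_streamlines), function(i) {
      for (try in 1:50) {
        s <- center + .smooth_offsets(n_pts, clen, spec$radial_jitter_sd)
        len <- streamline_length(s)
        if (len >= spec$length_range[1L] && len <= spec$length_range[2L])
          return(s)
      }
      stop("could not draw a streamline inside length_range", call. = FALSE)
    })
  })
  lab <- if (is.null(spec$pair)) "u_fiber" else paste(spec$pair, collapse = "-")
  bundle(streams, grid = grid, label = lab)
}

#' Generate a spurious (anatomically implausible) bundle
#'
#' Streamlines are built as high-curvature smoothed random walks launched
#' near one endpoint with only weak drift toward the other, with an optional
#' loop: the morphology of false positive tractography (abrupt directional
#' changes, random trajectories, looping). By construction such bundles fail
#' the plausibility scorer's smoothness and endpoint-coverage checks at
#' default thresholds.
#'
#' @param spec A [bundle_spec()] with `kind = "spurious"`.
#' @inheritParams generate_u_bundle
#' @return A [bundle()].
#' @export
generate_spurious_bundle <- function(spec, seed = NULL, grid = default_grid()) {
  if (spec$kind != "spurious") stop("spec$kind must be 'spurious'", call. = FALSE)
  a <- spec$endpoints[1L, ]; b <- spec$endpoints[2L, ]
  n_steps <- max(20L, as.integer(ceiling(1.5 * sqrt(sum((b - a)^2)))))
  lim <- grid$shape  # keep walks inside the grid
  streams <- .with_seed(seed, {
    lapply(seq_len(spec$n_streamlines), function(i) {
      p <- a + stats::rnorm(3L, 0, 3)
      dir <- (b - a) / sqrt(sum((b - a)^2))
      pts <- matrix(0, n_steps + 1L, 3L)
      pts[1L, ] <- p
      for (k in seq_len(n_steps)) {
        drift <- (b - p); drift <- drift / max(sqrt(sum(drift^2)), 1)
        dir <- dir + stats::rnorm(3L, 0, 1.2) + 0.1 * drift
        dir <- dir / sqrt(sum(dir^2))
        p <- p + dir
        p <- pmin(pmax(p, 2), lim - 2)
        pts[k + 1L, ] <- p
      }
      step <- diff(pts)
      keep <- c(TRUE, rowSums(step^2) > 1e-12)
      pts[keep, , drop = FALSE]
    })
  })
  lab <- if (is.null(spec$pair)) "spurious" else paste(spec$pair, collapse = "-")
  bundle(streams, grid = grid, label = lab)
}

#' Generate a bundle according to its spec kind
#' @inheritParams generate_u_bundle
#' @export
generate_bundle <- function(spec, seed = NULL, grid = default_grid()) {
  switch(spec$kind,
         u_fiber = generate_u_bundle(spec, seed = seed, grid = grid),
         spurious = generate_spurious_bundle(spec, seed = seed, grid = grid),
         absent = bundle(list(), grid = grid,
                         label = if (is.null(spec$pair)) "absent"
                                 else paste(spec$pair, collapse = "-")))
}

#' Cohort specification for the status-level simulator
#'
#' @param n_subjects Number of subjects.
#' @param pairs Data frame with columns `area_a`, `area_b` (canonical);
#'   defaults to all 91 pairs.
#' @param prevalence Probability that a subject yields an anatomically
#'   plausible bundle, recycled or named by `"area_a|area_b"` key.
#' @param implausible_rate Probability that a failed (non-plausible) draw is
#'   a spurious bundle instead of an absent one.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, pairs = enumerate_pairs(),
                        prevalence = 0.9, implausible_rate = 0,
                        seed = 1L) {
  if (n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  key <- .pair_key(pairs$area_a, pairs$area_b)
  if (!is.null(names(prevalence))) {
    prev <- prevalence[key]
    if (anyNA(prev)) stop("prevalence missing for some pairs", call. = FALSE)
  } else {
    prev <- rep_len(prevalence, nrow(pairs))
  }
  if (any(prev < 0 | prev > 1) || implausible_rate < 0 || implausible_rate > 1)
    stop("probabilities must be in [0, 1]", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), pairs = pairs,
                 prevalence = stats::setNames(as.numeric(prev), key),
                 implausible_rate = implausible_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort: per-subject statuses and (optionally) bundles
#'
#' For each subject x pair, the bundle status is drawn as plausible with
#' probability `prevalence`, otherwise spurious with probability
#' `implausible_rate`, otherwise absent. The returned ledger is the ground
#' truth used for parameter-recovery tests. With `make_bundles = TRUE`,
#' matching synthetic bundles are generated (U-fibers for plausible,
#' random-walk bundles for implausible, empty for absent) and optionally
#' written as TRK files under `out_dir/sub-XXX/pair-A_B.trk`.
#'
#' @param spec A [cohort_spec()].
#' @param make_bundles Generate geometry as well as statuses (default FALSE:
#'   status-level simulation only).
#' @param out_dir If non-NULL (and `make_bundles`), write TRK files plus
#'   `ledger.csv` here.
#' @param grid Grid for generated bundles.
#' @param n_streamlines Streamline count per generated bundle.
#' @return A list with `ledger` (data frame: `area_a`, `area_b`, `subject`,
#'   `status`) and, if requested, `bundles[[subject]][[pair_key]]`.
#' @export
generate_cohort <- function(spec, make_bundles = FALSE, out_dir = NULL,
                            grid = default_grid(), n_streamlines = 50L) {
  stopifnot(inherits(spec, "cohort_spec"))
  pairs <- spec$pairs
  key <- .pair_key(pairs$area_a, pairs$area_b)
  subjects <- sprintf("sub-%03d", seq_len(spec$n_subjects))
  out <- .with_seed(spec$seed, {
    status <- matrix("", nrow = nrow(pairs), ncol = spec$n_subjects)
    for (j in seq_len(spec$n_subjects)) {
      u1 <- stats::runif(nrow(pairs))
      u2 <- stats::runif(nrow(pairs))
      status[, j] <- ifelse(u1 < spec$prevalence[key], "plausible",
                     ifelse(u2 < spec$implausible_rate, "implausible",
                            "absent"))
    }
    bundles <- NULL
    if (make_bundles) {
      bundles <- lapply(seq_len(spec$n_subjects), function(j) {
        bl <- lapply(seq_len(nrow(pairs)), function(i) {
          kind <- switch(status[i, j], plausible = "u_fiber",
                         implausible = "spurious", absent = "absent")
          sp <- bundle_spec(pair = c(pairs$area_a[i], pairs$area_b[i]),
                            kind = kind,
                            n_streamlines = if (kind == "absent") 0L
                                            else n_streamlines)
          generate_bundle(sp, grid = grid)
        })
        stats::setNames(bl, key)
      })
      names(bundles) <- subjects
    }
    list(status = status, bundles = bundles)
  })
  ledger <- data.frame(
    area_a = rep(pairs$area_a, times = spec$n_subjects),
    area_b = rep(pairs$area_b, times = spec$n_subjects),
    subject = rep(subjects, each = nrow(pairs)),
    status = as.vector(out$status),
    stringsAsFactors = FALSE
  )
  if (!is.null(out_dir) && make_bundles) {
    for (j in seq_along(subjects)) {
      d <- file.path(out_dir, subjects[j])
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      for (i in seq_len(nrow(pairs))) {
        fn <- sprintf("pair-%s_%s.trk", gsub("/", "+", pairs$area_a[i]),
                      gsub("/", "+", pairs$area_b[i]))
        write_trk(out$bundles[[j]][[i]], file.path(d, fn))
      }
    }
    utils::write.csv(ledger, file.path(out_dir, "ledger.csv"),
                     row.names = FALSE)
  }
  list(ledger = ledger, bundles = out$bundles)
}

#' Scan-rescan perturbation magnitudes
#'
#' Within-subject (scan-rescan) perturbations are small; between-subject
#' differences are larger and include a rigid offset standing in for residual
#' misalignment after normalization to a shared space.
#'
#' @param within_jitter_sd Smooth jitter SD for rescans, mm (default 0.5).
#' @param between_jitter_sd Smooth jitter SD between subjects, mm
#'   (default 2.5).
#' @param rigid_shift_sd SD of the random rigid translation applied in
#'   between mode, mm (default 1).
#' @return An object of class `retest_spec`.
#' @export
retest_spec <- function(within_jitter_sd = 0.5, between_jitter_sd = 2.5,
                        rigid_shift_sd = 1) {
  if (within_jitter_sd >= between_jitter_sd)
    stop("within_jitter_sd must be smaller than between_jitter_sd",
         call. = FALSE)
  structure(list(within_jitter_sd = within_jitter_sd,
                 between_jitter_sd = between_jitter_sd,
                 rigid_shift_sd = rigid_shift_sd), class = "retest_spec")
}

#' Perturbed copy of a bundle (scan-rescan or between-subject replicate)
#'
#' Applies smooth correlated per-streamline jitter with SD
#' `within_jitter_sd` (`mode = "within"`) or `between_jitter_sd` plus a
#' random rigid shift (`mode = "between"`).
#'
#' @param b A non-empty [bundle()].
#' @param retest A [retest_spec()].
#' @param mode `"within"` or `"between"`.
#' @param seed Integer seed.
#' @return A perturbed [bundle()].
#' @export
make_retest_pair <- function(b, retest = retest_spec(),
                             mode = c("within", "between"), seed = NULL) {
  mode <- match.arg(mode)
  if (length(b$streamlines) == 0L)
    stop("cannot perturb an empty bundle", call. = FALSE)
  sd_jit <- if (mode == "within") retest$within_jitter_sd
            else retest$between_jitter_sd
  .with_seed(seed, {
    shift <- if (mode == "between")
      stats::rnorm(3L, 0, retest$rigid_shift_sd) else c(0, 0, 0)
    b$streamlines <- lapply(b$streamlines, function(s) {
      len <- streamline_length(s)
      out <- s + .smooth_offsets(nrow(s), len, sd_jit)
      sweep(out, 2L, shift, "+")
    })
    b
  })
}

#' Generate a scan-rescan cohort for test-retest analysis
#'
#' For each pair a template U-fiber bundle is built between the synthetic
#' area centres; each subject is a between-mode perturbation of the template
#' (anatomical individuality), and each of the two scans is a within-mode
#' perturbation of the subject's bundle (scan noise). All subjects share one
#' grid, so between-subject comparisons need no registration.
#'
#' @param n_subjects Number of subjects (>= 2 for between-subject use).
#' @param pairs Data frame of pairs (columns `area_a`, `area_b`).
#' @param retest A [retest_spec()].
#' @param seed Integer seed.
#' @param n_streamlines Streamlines per bundle.
#' @param grid Shared [voxel_grid()].
#' @return A list of class `retest_cohort`: `pairs`, `subjects`, `grid`, and
#'   `scans[[scan]][[subject]][[pair_key]]` bundles (scans `"scan1"`,
#'   `"scan2"`).
#' @export
generate_retest_cohort <- function(n_subjects, pairs, retest = retest_spec(),
                                   seed = 1L, n_streamlines = 50L,
                                   grid = default_grid()) {
  key <- .pair_key(pairs$area_a, pairs$area_b)
  subjects <- sprintf("sub-%03d", seq_len(n_subjects))
  scans <- .with_seed(seed, {
    templates <- lapply(seq_len(nrow(pairs)), function(i) {
      sp <- bundle_spec(pair = c(pairs$area_a[i], pairs$area_b[i]),
                        n_streamlines = n_streamlines)
      generate_u_bundle(sp, grid = grid)
    })
    per_subject <- lapply(subjects, function(su) {
      stats::setNames(lapply(templates, function(tb)
        make_retest_pair(tb, retest, mode = "between")), key)
    })
    list(
      scan1 = lapply(per_subject, function(bl)
        lapply(bl, make_retest_pair, retest = retest, mode = "within")),
      scan2 = lapply(per_subject, function(bl)
        lapply(bl, make_retest_pair, retest = retest, mode = "within"))
    )
  })
  scans <- lapply(scans, stats::setNames, subjects)
  structure(list(pairs = pairs, subjects = subjects, grid = grid,
                 scans = scans), class = "retest_cohort")
}
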