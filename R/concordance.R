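# Aggregation of connection classifications into confusion counts and
# concordance statistics (overall and per partition), and test-retest
# summaries built on the bundle comparison metrics.

#' Round half up
#'
#' Percentages are reported round-half-up to integers (66/91 -> 73), unlike
#' base R's round-half-even.
#'
#' @param x Numeric.
#' @param digits Decimal digits (default 0).
#' @return Rounded value.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Confusion counts of a classification table
#'
#' Counts RTP/TP/TN/FP/FN labels over a scope: `"overall"` (all pairs) or a
#' partition name (pairs with at least one member area in the partition).
#' `tp` includes the robust subset (`rtp <= tp`); `fp` pools both subtypes.
#'
#' @param classifications Data frame with columns `area_a`, `area_b`,
#'   `label` (as from [classify_ledger()] or [paper_classifications()]).
#' @param scope `"overall"` or one of [pfc_partitions()].
#' @return A list of class `confusion_counts`: `scope`, `tp`, `rtp`, `tn`,
#'   `fp`, `fn`, `total`.
#' @export
confusion_counts <- function(classifications, scope = "overall") {
  cls <- classifications
  if (!all(c("area_a", "area_b", "label") %in% names(cls)))
    stop("classifications must have columns area_a, area_b, label",
         call. = FALSE)
  if (!identical(scope, "overall")) {
    want <- pairs_for_partition(scope)
    want_key <- .pair_key(want$area_a, want$area_b)
    have_key <- .pair_key(cls$area_a, cls$area_b)
    missing <- setdiff(want_key, have_key)
    if (length(missing) > 0L)
      stop("classifications do not cover the ", scope, " scope; missing: ",
           paste(missing, collapse = ", "), call. = FALSE)
    cls <- cls[have_key %in% want_key, , drop = FALSE]
  }
  lab <- cls$label
  structure(list(
    scope = scope,
    tp = sum(lab %in% c("TP", "RTP")),
    rtp = sum(lab == "RTP"),
    tn = sum(lab == "TN"),
    fp = sum(lab == "FP"),
    fn = sum(lab == "FN"),
    total = length(lab)
  ), class = "confusion_counts")
}

#' Concordance statistics from confusion counts
#'
#' Accuracy `(tp+tn)/total`, sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)` and precision `tp/(tp+fp)`, as raw percentages and
#' round-half-up integers (the reporting convention). A zero denominator
#' yields `NA` ("not applicable") for that statistic.
#'
#' @param counts A [confusion_counts()] object.
#' @return A data frame with columns `statistic`, `raw` (percent) and
#'   `rounded` (integer percent).
#' @export
concordance_stats <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  raw <- c(
    accuracy = ratio(counts$tp + counts$tn, counts$total),
    sensitivity = ratio(counts$tp, counts$tp + counts$fn),
    specificity = ratio(counts$tn, counts$tn + counts$fp),
    precision = ratio(counts$tp, counts$tp + counts$fp)
  )
  data.frame(statistic = names(raw), raw = unname(raw),
             rounded = round_half_up(unname(raw)),
             stringsAsFactors = FALSE)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("[%s] TP %d (RTP %d) | TN %d | FP %d | FN %d (n = %d)\n",
              x$scope, x$tp, x$rtp, x$tn, x$fp, x$fn, x$total))
  invisible(x)
}

.partition_of_pair <- function(area_a, area_b) {
  areas <- pfc_areas()
  pa <- areas$partition[match(area_a, areas$label)]
  pb <- areas$partition[match(area_b, areas$label)]
  mapply(function(x, y) unique(c(x, y)), pa, pb, SIMPLIFY = FALSE)
}

#' Pairwise test-retest comparison of a cohort
#'
#' `mode = "within"` compares, for every subject and pair, the bundle from
#' scan 1 with the bundle from scan 2. `mode = "between"` compares the
#' scan-1 bundles of all unordered subject pairs (or a seeded random
#' subsample of `max_comparisons` of them) for every pair. Missing or empty
#' bundles are skipped with a warning.
#'
#' @param cohort A `retest_cohort` (see [generate_retest_cohort()]): a list
#'   with `pairs`, `subjects`, `grid` and `scans[[scan]][[subject]][[pair]]`.
#' @param mode `"within"` or `"between"`.
#' @param max_comparisons Cap on between-subject comparisons per pair
#'   (default: all when <= 50 subjects, else a seeded subsample of 1000).
#' @param seed Seed for the subsample draw.
#' @return A list with `results` (data frame: pair, subjects, `wdice`,
#'   `bundle_adjacency_mm`, `overlap_voxels`) and `summary` (see
#'   [retest_summary()]).
#' @export
retest_compare <- function(cohort, mode = c("within", "between"),
                           max_comparisons = NULL, seed = 1L) {
  mode <- match.arg(mode)
  pairs <- cohort$pairs
  subjects <- cohort$subjects
  key <- .pair_key(pairs$area_a, pairs$area_b)
  if (mode == "between" && length(subjects) < 2L)
    stop("between-subject comparison needs >= 2 subjects", call. = FALSE)
  if (mode == "within" &&
      !all(c("scan1", "scan2") %in% names(cohort$scans)))
    stop("within-subject comparison needs two scans per subject",
         call. = FALSE)

  # density maps are the unit of comparison; compute each bundle's map once
  dmap <- function(scan, subject, k) {
    b <- cohort$scans[[scan]][[subject]][[k]]
    if (is.null(b) || length(b$streamlines) == 0L) return(NULL)
    density_map(b, grid = cohort$grid)
  }

  rows <- list()
  skipped <- 0L
  if (mode == "within") {
    for (su in subjects) {
      for (i in seq_along(key)) {
        dA <- dmap("scan1", su, key[i]); dB <- dmap("scan2", su, key[i])
        if (is.null(dA) || is.null(dB)) { skipped <- skipped + 1L; next }
        rows[[length(rows) + 1L]] <- data.frame(
          area_a = pairs$area_a[i], area_b = pairs$area_b[i],
          subject_a = su, subject_b = su,
          wdice = weighted_dice(dA, dB),
          bundle_adjacency_mm = bundle_adjacency(dA, dB),
          stringsAsFactors = FALSE)
      }
    }
  } else {
    combos <- utils::combn(length(subjects), 2L)
    if (is.null(max_comparisons))
      max_comparisons <- if (length(subjects) <= 50L) ncol(combos) else 1000L
    if (ncol(combos) > max_comparisons) {
      pick <- .with_seed(seed,
                         sample.int(ncol(combos), max_comparisons))
      combos <- combos[, pick, drop = FALSE]
    }
    for (i in seq_along(key)) {
      maps <- lapply(subjects, function(su) dmap("scan1", su, key[i]))
      for (c_i in seq_len(ncol(combos))) {
        ja <- combos[1L, c_i]; jb <- combos[2L, c_i]
        dA <- maps[[ja]]; dB <- maps[[jb]]
        if (is.null(dA) || is.null(dB)) { skipped <- skipped + 1L; next }
        rows[[length(rows) + 1L]] <- data.frame(
          area_a = pairs$area_a[i], area_b = pairs$area_b[i],
          subject_a = subjects[ja], subject_b = subjects[jb],
          wdice = weighted_dice(dA, dB),
          bundle_adjacency_mm = bundle_adjacency(dA, dB),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (skipped > 0L)
    warning(skipped, " comparisons skipped (missing or empty bundles)",
            call. = FALSE)
  results <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(area_a = character(), area_b = character(),
               subject_a = character(), subject_b = character(),
               wdice = numeric(), bundle_adjacency_mm = numeric())
  results$mode <- mode
  list(results = results, summary = retest_summary(results))
}

#' Summarize test-retest comparisons per scope
#'
#' Pools comparisons over all pairs in each scope (overall plus every
#' partition touched) and reports mean and SD of weighted Dice and bundle
#' adjacency.
#'
#' @param results The `results` data frame from [retest_compare()].
#' @return A data frame: `scope`, `mode`, `n`, `wdice_mean`, `wdice_sd`,
#'   `ba_mean`, `ba_sd`.
#' @export
retest_summary <- function(results) {
  if (nrow(results) == 0L)
    return(data.frame(scope = character(), mode = character(), n = integer(),
                      wdice_mean = numeric(), wdice_sd = numeric(),
                      ba_mean = numeric(), ba_sd = numeric()))
  parts <- .partition_of_pair(results$area_a, results$area_b)
  scopes <- c("overall", pfc_partitions())
  rows <- lapply(scopes, function(sc) {
    sel <- if (sc == "overall") rep(TRUE, nrow(results)) else
      vapply(parts, function(p) sc %in% p, logical(1L))
    if (!any(sel)) return(NULL)
    r <- results[sel, , drop = FALSE]
    data.frame(scope = sc, mode = r$mode[1L], n = nrow(r),
               wdice_mean = mean(r$wdice), wdice_sd = stats::sd(r$wdice),
               ba_mean = mean(r$bundle_adjacency_mm),
               ba_sd = stats::sd(r$bundle_adjacency_mm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full concordance report
#'
#' Confusion counts and concordance statistics overall and for each of the
#' five partitions, with optional test-retest summaries, as both a
#' machine-readable list and a formatted text table.
#'
#' @param classifications Classification table (see [confusion_counts()]).
#' @param retest Optional list with `within` and/or `between` entries, each a
#'   [retest_summary()] data frame (or the list returned by
#'   [retest_compare()]).
#' @return A list of class `concordance_report`: `counts` (data frame, one
#'   row per scope), `stats` (data frame), `retest` (or `NULL`), `text`
#'   (character vector of formatted lines) and `json` (jsonlite string).
#' @export
concordance_report <- function(classifications, retest = NULL) {
  scopes <- c("overall", pfc_partitions())
  cnt_rows <- list(); stat_rows <- list()
  for (sc in scopes) {
    ct <- confusion_counts(classifications, sc)
    st <- concordance_stats(ct)
    cnt_rows[[sc]] <- data.frame(scope = sc, tp = ct$tp, rtp = ct$rtp,
                                 tn = ct$tn, fp = ct$fp, fn = ct$fn,
                                 total = ct$total, stringsAsFactors = FALSE)
    st$scope <- sc
    stat_rows[[sc]] <- st
  }
  counts <- do.call(rbind, cnt_rows); rownames(counts) <- NULL
  stats_df <- do.call(rbind, stat_rows); rownames(stats_df) <- NULL
  if (!is.null(retest)) {
    retest <- lapply(retest, function(x) if (is.list(x) && !is.data.frame(x))
      x$summary else x)
  }
  text <- c(
    "Concordance with histology",
    sprintf("%-12s %4s %5s %4s %4s %4s | %4s %4s %4s %4s",
            "scope", "TP", "(RTP)", "TN", "FP", "FN",
            "acc", "sens", "spec", "prec"),
    vapply(seq_len(nrow(counts)), function(i) {
      st <- stats_df[stats_df$scope == counts$scope[i], ]
      g <- function(s) {
        v <- st$rounded[st$statistic == s]
        if (is.na(v)) "n/a" else sprintf("%d%%", v)
      }
      sprintf("%-12s %4d %5s %4d %4d %4d | %4s %4s %4s %4s",
              counts$scope[i], counts$tp[i],
              sprintf("(%d)", counts$rtp[i]), counts$tn[i], counts$fp[i],
              counts$fn[i], g("accuracy"), g("sensitivity"),
              g("specificity"), g("precision"))
    }, character(1L))
  )
  if (!is.null(retest)) {
    for (m in names(retest)) {
      rs <- retest[[m]]
      text <- c(text, "", sprintf("Test-retest (%s)", m),
                vapply(seq_len(nrow(rs)), function(i)
                  sprintf("%-12s wDice %.2f +/- %.2f | BA %.2f +/- %.2f mm (n=%d)",
                          rs$scope[i], rs$wdice_mean[i], rs$wdice_sd[i],
                          rs$ba_mean[i], rs$ba_sd[i], rs$n[i]),
                  character(1L)))
    }
  }
  payload <- list(counts = counts, stats = stats_df)
  if (!is.null(retest)) payload$retest <- retest
  structure(list(counts = counts, stats = stats_df, retest = retest,
                 text = text,
                 json = as.character(jsonlite::toJSON(payload, digits = NA,
                                                      dataframe = "rows"))),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}
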