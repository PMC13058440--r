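#' Prefrontal areas and their partition scheme
#'
#' The analysis covers 14 cytoarchitectonic (Brodmann) areas of the prefrontal
#' cortex, grouped into the five canonical partitions: dorsolateral PFC
#' (areas 8, 9, 46, 9/46), ventrolateral PFC (44, 45, 47), orbitofrontal
#' cortex (11, 13, 14), frontal pole (10) and anterior cingulate cortex
#' (24, 25, 32). Area 14 is kept as a single label; its approximation by
#' orbitofrontal parcels in surface atlases is metadata only.
#'
#' @return A data frame with columns `label` (character) and `partition`
#'   (character, one of `"dlPFC"`, `"vlPFC"`, `"OFC"`, `"FrontalPole"`,
#'   `"ACC"`), 14 rows.
#' @examples
#' table(pfc_areas()$partition)
#' @export
pfc_areas <- function() {
  data.frame(
    label = c("8", "9", "46", "9/46",
              "44", "45", "47",
              "11", "13", "14",
              "10",
              "24", "25", "32"),
    partition = rep(c("dlPFC", "vlPFC", "OFC", "FrontalPole", "ACC"),
                    times = c(4, 3, 3, 1, 3)),
    stringsAsFactors = FALSE
  )
}

#' @rdname pfc_areas
#' @export
pfc_partitions <- function() c("dlPFC", "vlPFC", "OFC", "FrontalPole", "ACC")

.check_area <- function(label) {
  bad <- setdiff(label, pfc_areas()$label)
  if (length(bad) > 0L)
    stop("unknown area label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(label)
}

#' Canonical form of an unordered area pair
#'
#' A connection is an unordered pair of distinct areas; the canonical form
#' sorts the two labels lexicographically so that ("9","46") and ("46","9")
#' denote the same connection.
#'
#' @param a,b Area labels (character vectors of equal length).
#' @return A data frame with columns `area_a` and `area_b`, `area_a <= area_b`
#'   in C-locale string order.
#' @examples
#' canonical_pair("9", "46")
#' @export
canonical_pair <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  .check_area(a); .check_area(b)
  if (any(a == b)) stop("a pair must join two distinct areas", call. = FALSE)
  sw <- .str_gt(a, b)
  tmp <- a[sw]; a[sw] <- b[sw]; b[sw] <- tmp
  data.frame(area_a = a, area_b = b, stringsAsFactors = FALSE)
}

# C-locale string comparison, independent of the session locale
.str_gt <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  vapply(seq_len(n), function(i) {
    r <- utf8ToInt(a[i]); s <- utf8ToInt(b[i])
    k <- min(length(r), length(s))
    d <- which(r[seq_len(k)] != s[seq_len(k)])
    if (length(d) == 0L) length(r) > length(s) else r[d[1L]] > s[d[1L]]
  }, logical(1L))
}

.pair_key <- function(a, b) paste(a, b, sep = "|")

#' Enumerate the 91 studied connection pairs
#'
#' All unordered pairs of distinct areas among the 14 prefrontal areas:
#' choose(14, 2) = 91 connections, in a deterministic lexicographic order.
#'
#' @return A data frame with columns `area_a`, `area_b` (canonical order),
#'   91 rows.
#' @examples
#' nrow(enumerate_pairs())
#' @export
enumerate_pairs <- function() {
  labs <- sort(pfc_areas()$label, method = "radix")
  idx <- utils::combn(length(labs), 2L)
  data.frame(area_a = labs[idx[1L, ]], area_b = labs[idx[2L, ]],
             stringsAsFactors = FALSE)
}

.load_fixture <- function(name) {
  path <- system.file("extdata", name, package = "tractconcord")
  if (!nzchar(path)) stop("packaged fixture not found: ", name, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' The histological ground-truth connectivity matrix
#'
#' Per-pair precedence in the tract-tracing literature: `present` for
#' connections consistently reported across histological studies, `absent`
#' for connections without precedence (or reported only in isolated,
#' inconsistent instances). 72 of the 91 pairs are present and 19 absent.
#' Rows where the source descriptions conflict are flagged `ambiguous`.
#'
#' @return A data frame with columns `area_a`, `area_b`, `precedence`
#'   (`"present"`/`"absent"`) and `ambiguous` (logical); 91 rows.
#' @examples
#' table(histology_matrix()$precedence)
#' @export
histology_matrix <- function() {
  gt <- .load_fixture("ground_truth.csv")
  gt$ambiguous <- as.logical(gt$ambiguous)
  gt
}

#' Histological precedence of a connection pair
#'
#' @param a,b Area labels (order irrelevant).
#' @return `"present"` or `"absent"`.
#' @examples
#' precedence("9", "10")   # "present"
#' precedence("44", "10")  # "absent"
#' @export
precedence <- function(a, b) {
  p <- canonical_pair(a, b)
  gt <- histology_matrix()
  m <- match(.pair_key(p$area_a, p$area_b), .pair_key(gt$area_a, gt$area_b))
  gt$precedence[m]
}

#' Connection pairs touching a partition
#'
#' Returns every pair with at least one member area in the given partition;
#' intra-partition pairs are included. This is the scope convention used for
#' the per-partition concordance breakdowns, so pairs spanning two partitions
#' contribute to both.
#'
#' @param partition One of [pfc_partitions()].
#' @return A data frame with columns `area_a`, `area_b`.
#' @examples
#' nrow(pairs_for_partition("dlPFC"))        # 46
#' nrow(pairs_for_partition("FrontalPole"))  # 13
#' @export
pairs_for_partition <- function(partition) {
  if (!partition %in% pfc_partitions())
    stop("unknown partition: ", partition, call. = FALSE)
  areas <- pfc_areas()
  members <- areas$label[areas$partition == partition]
  pr <- enumerate_pairs()
  pr[pr$area_a %in% members | pr$area_b %in% members, , drop = FALSE]
}

#' Per-pair classification outcomes transcribed from the source study
#'
#' The published connection-level outcome for each of the 91 pairs:
#' `RTP` (robust true positive), `TP`, `TN`, `FP` or `FN`, with the false
#' positive subtype (`no_precedence` for reconstructed pairs without
#' histological precedence, `implausible_with_precedence` for pairs with
#' precedence whose reconstructions were consistently implausible). Rows
#' whose label had to be reconciled across conflicting descriptions are
#' flagged `ambiguous`.
#'
#' @return A data frame with columns `area_a`, `area_b`, `label`,
#'   `fp_subtype`, `ambiguous`; 91 rows.
#' @examples
#' table(paper_classifications()$label)
#' @export
paper_classifications <- function() {
  led <- .load_fixture("paper_ledger.csv")
  led$ambiguous <- as.logical(led$ambiguous)
  led
}
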