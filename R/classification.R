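# Bundle-status assessment (a rule-based proxy for visual QA), max-length
# calibration, and prevalence-thresholded connection classification.

#' Default thresholds for the rule-based plausibility scorer
#'
#' @param sparse Minimum streamline count for a bundle to count as
#'   reconstructed at all; below it the status is `absent` (default 20,
#'   the negligible-reconstruction bound).
#' @param endpoint_min Minimum fraction of streamlines with both endpoints
#'   inside their (dilated) designated ROIs (default 0.8).
#' @param angle_max Maximum mean absolute turning angle, degrees per step at
#'   1 mm resampling (default 35).
#' @param support_min Minimum fraction of the density-map support occupied by
#'   its largest 26-connected component (default 0.75).
#' @param roi_dilate_mm ROI dilation radius in mm applied before the endpoint
#'   check (default 2).
#' @return A named list of thresholds.
#' @export
plausibility_thresholds <- function(sparse = 20L, endpoint_min = 0.8,
                                    angle_max = 35, support_min = 0.75,
                                    roi_dilate_mm = 2) {
  list(sparse = sparse, endpoint_min = endpoint_min, angle_max = angle_max,
       support_min = support_min, roi_dilate_mm = roi_dilate_mm)
}

#' Spherical ROI mask on a grid
#'
#' @param grid A [voxel_grid()].
#' @param center World-mm centre (length 3).
#' @param radius_mm Sphere radius in mm (voxel centres within the radius are
#'   included).
#' @return A list with `mask` (logical array) and `grid`.
#' @export
sphere_mask <- function(grid, center, radius_mm) {
  dimg <- grid$shape
  idx <- as.matrix(expand.grid(x = 0:(dimg[1L] - 1L), y = 0:(dimg[2L] - 1L),
                               z = 0:(dimg[3L] - 1L)))
  ctr <- .voxel_to_world(idx + 0.5, grid)
  d2 <- (ctr[, 1L] - center[1L])^2 + (ctr[, 2L] - center[2L])^2 +
        (ctr[, 3L] - center[3L])^2
  list(mask = array(d2 <= radius_mm^2, dim = dimg), grid = grid)
}

#' Dilate a binary mask by a metric radius
#'
#' @param roi A list with `mask` and `grid` (as from [read_mask()] or
#'   [sphere_mask()]).
#' @param mm Dilation radius in mm (0 returns the mask unchanged).
#' @return The dilated mask (same structure).
#' @export
dilate_mask <- function(roi, mm) {
  if (mm <= 0) return(roi)
  vs <- .grid_voxel_size(roi$grid)
  r <- ceiling(mm / vs)
  offs <- as.matrix(expand.grid(dx = -r[1L]:r[1L], dy = -r[2L]:r[2L],
                                dz = -r[3L]:r[3L]))
  mmoff <- sweep(offs, 2L, vs, "*")
  offs <- offs[rowSums(mmoff^2) <= mm^2, , drop = FALSE]
  dimg <- roi$grid$shape
  src <- which(roi$mask, arr.ind = TRUE) - 1L
  out <- array(FALSE, dim = dimg)
  for (k in seq_len(nrow(offs))) {
    v <- sweep(src, 2L, offs[k, ], "+")
    ok <- v[, 1L] >= 0 & v[, 1L] < dimg[1L] & v[, 2L] >= 0 &
          v[, 2L] < dimg[2L] & v[, 3L] >= 0 & v[, 3L] < dimg[3L]
    v <- v[ok, , drop = FALSE]
    out[1L + v[, 1L] + dimg[1L] * (v[, 2L] + dimg[2L] * v[, 3L])] <- TRUE
  }
  list(mask = out, grid = roi$grid)
}

.in_mask <- function(points, roi) {
  dimg <- roi$grid$shape
  vox <- floor(.world_to_voxel(points, roi$grid))
  ok <- vox[, 1L] >= 0 & vox[, 1L] < dimg[1L] & vox[, 2L] >= 0 &
        vox[, 2L] < dimg[2L] & vox[, 3L] >= 0 & vox[, 3L] < dimg[3L]
  res <- logical(nrow(points))
  lin <- 1L + vox[ok, 1L] + dimg[1L] * (vox[ok, 2L] + dimg[2L] * vox[ok, 3L])
  res[ok] <- roi$mask[lin]
  res
}

#' Mean absolute turning angle of a bundle
#'
#' Streamlines are resampled at `step` mm; the turning angle at each interior
#' vertex is the angle between consecutive segments. Returns the mean over
#' all vertices of all streamlines, in degrees.
#'
#' @param b A [bundle()].
#' @param step Resampling step in mm (default 1).
#' @return Mean turning angle in degrees (NA for an empty bundle).
#' @export
mean_turning_angle <- function(b, step = 1) {
  angs <- unlist(lapply(b$streamlines, function(s) {
    r <- resample_streamline(s, step = step)
    if (nrow(r) < 3L) return(numeric(0L))
    v <- diff(r)
    n <- sqrt(rowSums(v^2))
    cosang <- rowSums(v[-nrow(v), , drop = FALSE] *
                      v[-1L, , drop = FALSE]) /
              (n[-length(n)] * n[-1L])
    acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  }))
  if (length(angs) == 0L) return(NA_real_)
  mean(angs)
}

# fraction of the support in its largest 26-connected component
.largest_component_fraction <- function(support) {
  n <- nrow(support)
  if (n == 0L) return(NA_real_)
  key <- function(v) paste(v[, 1L], v[, 2L], v[, 3L], sep = ",")
  keys <- key(support)
  idx <- stats::setNames(seq_len(n), keys)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  visited <- logical(n)
  best <- 0L
  for (start in seq_len(n)) {
    if (visited[start]) next
    queue <- start; visited[start] <- TRUE; size <- 0L
    while (length(queue) > 0L) {
      cur <- queue[[1L]]; queue <- queue[-1L]; size <- size + 1L
      nb <- sweep(offs, 2L, as.integer(support[cur, ]), "+")
      hit <- idx[key(nb)]
      hit <- hit[!is.na(hit)]
      new <- hit[!visited[hit]]
      if (length(new) > 0L) {
        visited[new] <- TRUE
        queue <- c(queue, new)
      }
    }
    best <- max(best, size)
  }
  best / n
}

#' Rule-based bundle status assessment
#'
#' Operationalizes the visual-QA criteria as explicit rules (a proxy for
#' human raters, tuned only on synthetic data):
#' * `absent` if the streamline count is below `sparse`;
#' * `implausible` if any check fails:
#'   (a) the fraction of streamlines with both endpoints inside their
#'   designated (dilated) ROIs is below `endpoint_min`;
#'   (b) the mean absolute turning angle exceeds `angle_max` degrees;
#'   (c) the largest connected component of the density support holds less
#'   than `support_min` of the support;
#' * `plausible` otherwise.
#'
#' @param b A [bundle()].
#' @param roi_a,roi_b Endpoint ROI masks (lists with `mask`, `grid`).
#' @param thresholds See [plausibility_thresholds()].
#' @return A list of class `bundle_status` with `value`
#'   (`"plausible"`/`"implausible"`/`"absent"`) and `diagnostics`.
#' @export
assess_plausibility <- function(b, roi_a, roi_b,
                                thresholds = plausibility_thresholds()) {
  if (missing(roi_a) || missing(roi_b) || is.null(roi_a) || is.null(roi_b))
    stop("endpoint ROI masks are required", call. = FALSE)
  n <- length(b$streamlines)
  diag <- list(n_streamlines = n, endpoint_fraction = NA_real_,
               mean_turning_angle_deg = NA_real_,
               largest_component_fraction = NA_real_)
  mk <- function(value) structure(list(value = value, diagnostics = diag),
                                  class = "bundle_status")
  if (n < thresholds$sparse) return(mk("absent"))
  da <- dilate_mask(roi_a, thresholds$roi_dilate_mm)
  db <- dilate_mask(roi_b, thresholds$roi_dilate_mm)
  first <- t(vapply(b$streamlines, function(s) s[1L, ], numeric(3L)))
  last <- t(vapply(b$streamlines, function(s) s[nrow(s), ], numeric(3L)))
  hits <- (.in_mask(first, da) & .in_mask(last, db)) |
          (.in_mask(first, db) & .in_mask(last, da))
  diag$endpoint_fraction <- mean(hits)
  diag$mean_turning_angle_deg <- mean_turning_angle(b)
  dm <- density_map(b)
  diag$largest_component_fraction <-
    .largest_component_fraction(support_voxels(dm))
  if (diag$endpoint_fraction < thresholds$endpoint_min ||
      diag$mean_turning_angle_deg > thresholds$angle_max ||
      diag$largest_component_fraction < thresholds$support_min)
    return(mk("implausible"))
  mk("plausible")
}

#' Calibrate a per-tract maximum streamline length
#'
#' The final maximum length for a tract is the mean of the empirically
#' determined per-subject maxima plus 1.5 sample standard deviations
#' (n-1 denominator), accounting for individual variability.
#'
#' @param empirical_max_mm Numeric vector of per-subject maxima (>= 2 values,
#'   all positive).
#' @return Calibrated maximum length in mm.
#' @examples
#' calibrate_max_length(c(40, 50, 60))  # 65
#' @export
calibrate_max_length <- function(empirical_max_mm) {
  x <- as.numeric(empirical_max_mm)
  if (length(x) < 2L)
    stop("calibration needs >= 2 per-subject maxima", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("per-subject maxima must be positive and finite", call. = FALSE)
  mean(x) + 1.5 * stats::sd(x)
}

#' Classify one connection from its per-subject statuses
#'
#' Population-prevalence decision rules (all comparisons strict):
#' with `f_plaus`, `f_implaus`, `f_recon` the fractions of subjects whose
#' bundle is plausible, implausible, or either,
#' * precedence `present`: `f_plaus > t_rtp` -> `RTP`; else
#'   `f_plaus > t_tp` -> `TP`; else `f_implaus > t_tp` -> `FP`
#'   (subtype `implausible_with_precedence`); else `FN`.
#' * precedence `absent`: `f_recon > t_tp` -> `FP` (subtype
#'   `no_precedence`); else `TN`.
#'
#' A precedence-present pair where neither fraction clears `t_tp` but
#' `f_recon` does is classified `FN` with a warning (mixed sparse signal,
#' treated as a failed reconstruction).
#'
#' @param statuses Character vector of per-subject statuses
#'   (`"plausible"`/`"implausible"`/`"absent"`), one per subject.
#' @param precedence `"present"` or `"absent"`.
#' @param t_tp,t_rtp Prevalence thresholds, `0 < t_tp < t_rtp < 1`
#'   (defaults 0.5 and 0.8).
#' @return A one-row data frame: `label`, `fp_subtype`, `f_plausible`,
#'   `f_implausible`, `f_reconstructed`.
#' @export
classify_connection <- function(statuses, precedence, t_tp = 0.5,
                                t_rtp = 0.8) {
  statuses <- as.character(statuses)
  if (length(statuses) == 0L)
    stop("at least one subject status is required", call. = FALSE)
  bad <- setdiff(statuses, c("plausible", "implausible", "absent"))
  if (length(bad) > 0L)
    stop("invalid status value(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  if (!(t_tp > 0 && t_tp < t_rtp && t_rtp < 1))
    stop("thresholds must satisfy 0 < t_tp < t_rtp < 1", call. = FALSE)
  precedence <- match.arg(precedence, c("present", "absent"))
  f_plaus <- mean(statuses == "plausible")
  f_implaus <- mean(statuses == "implausible")
  f_recon <- f_plaus + f_implaus
  fp_subtype <- "none"
  if (precedence == "present") {
    if (f_plaus > t_rtp) label <- "RTP"
    else if (f_plaus > t_tp) label <- "TP"
    else if (f_implaus > t_tp) {
      label <- "FP"; fp_subtype <- "implausible_with_precedence"
    } else {
      label <- "FN"
      if (f_recon > t_tp)
        warning("mixed sparse signal (reconstructed in >",
                round(100 * t_tp), "% but neither status dominates); ",
                "classified FN", call. = FALSE)
    }
  } else {
    if (f_recon > t_tp) { label <- "FP"; fp_subtype <- "no_precedence" }
    else label <- "TN"
  }
  data.frame(label = label, fp_subtype = fp_subtype, f_plausible = f_plaus,
             f_implausible = f_implaus, f_reconstructed = f_recon,
             stringsAsFactors = FALSE)
}

#' Classify every pair of a status ledger
#'
#' @param ledger Data frame with columns `area_a`, `area_b`, `subject`,
#'   `status` (one row per pair x subject).
#' @param ground_truth Data frame with `area_a`, `area_b`, `precedence`
#'   (defaults to the packaged [histology_matrix()]).
#' @inheritParams classify_connection
#' @return A data frame with one row per pair present in the ledger:
#'   `area_a`, `area_b`, `label`, `fp_subtype`, `f_plausible`,
#'   `f_implausible`, `f_reconstructed`.
#' @export
classify_ledger <- function(ledger, ground_truth = histology_matrix(),
                            t_tp = 0.5, t_rtp = 0.8) {
  req <- c("area_a", "area_b", "subject", "status")
  if (!all(req %in% names(ledger)))
    stop("ledger must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (nrow(ledger) == 0L)
    stop("ledger contains no rows", call. = FALSE)
  key <- .pair_key(ledger$area_a, ledger$area_b)
  gt_key <- .pair_key(ground_truth$area_a, ground_truth$area_b)
  rows <- lapply(split(seq_len(nrow(ledger)), key), function(i) {
    k <- key[i[1L]]
    m <- match(k, gt_key)
    if (is.na(m)) stop("pair ", k, " not found in ground truth", call. = FALSE)
    cc <- classify_connection(ledger$status[i], ground_truth$precedence[m],
                              t_tp = t_tp, t_rtp = t_rtp)
    cbind(data.frame(area_a = ledger$area_a[i[1L]],
                     area_b = ledger$area_b[i[1L]],
                     stringsAsFactors = FALSE), cc)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$area_a, out$area_b, method = "radix"), , drop = FALSE]
}
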