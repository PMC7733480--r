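#' Connected components of a binary mask
#'
#' 26-connectivity labeling (switchable to 6); component volume is voxel
#' count times physical voxel volume.
#'
#' @param mask Binary `volume3d`.
#' @param connectivity 26 (default) or 6.
#' @return A data.frame with `component_id`, `voxels` and `volume_mm3`.
#'   The label array is attached as attribute `"labels"`.
#' @export
connected_components <- function(mask, connectivity = 26L) {
  stopifnot(inherits(mask, "volume3d"))
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  v <- as_binary_values(mask)
  lab <- cpp_label_components(as.vector(v > 0), dim(v), as.integer(connectivity))
  k <- max(lab)
  vv <- voxel_volume(mask)
  counts <- if (k > 0) tabulate(lab[lab > 0], k) else integer(0)
  out <- data.frame(component_id = seq_len(k), voxels = counts,
                    volume_mm3 = counts * vv)
  attr(out, "labels") <- array(lab, dim(v))
  out
}

#' Match predicted components to reference components
#'
#' A reference component counts as detected (TP) when at least one predicted
#' voxel overlaps it (adjustable to require an overlap fraction of the
#' reference volume). Each predicted component is assigned to the reference
#' component with which it shares the most voxels; predicted components
#' overlapping no reference component are false positives. Multiple
#' predicted components on one reference merge into a single TP, and the
#' pair Dice coefficient is computed between the reference component and
#' the union of its assigned predicted components.
#'
#' @param pred,ref Binary `volume3d` masks on a common grid.
#' @param connectivity Component connectivity (26 or 6).
#' @param min_overlap_frac Minimum overlap, as a fraction of the reference
#'   component volume, for a detection (default 0: one voxel suffices).
#' @return An object of class `detection_result`: data.frames `matched`
#'   (ref_id, pred_ids, dsc, ref_volume_mm3, pred_volume_mm3), `fn`
#'   (ref_id, ref_volume_mm3), `fp` (pred_id, pred_volume_mm3) and
#'   `n_scans = 1`.
#' @export
match_detections <- function(pred, ref, connectivity = 26L,
                             min_overlap_frac = 0) {
  stop_if_grid_mismatch(pred, ref, "pred and ref")
  rc <- connected_components(ref, connectivity)
  pc <- connected_components(pred, connectivity)
  rl <- attr(rc, "labels"); pl <- attr(pc, "labels")
  vv <- voxel_volume(ref)

  overlap <- matrix(0L, nrow(pc), nrow(rc))
  both <- which(rl > 0 & pl > 0)
  if (length(both)) {
    tab <- table(pred = pl[both], ref = rl[both])
    overlap[cbind(as.integer(rownames(tab))[row(tab)],
                  as.integer(colnames(tab))[col(tab)])] <- as.integer(tab)
  }
  # assign each predicted component to its max-overlap reference component
  assign_to <- rep(NA_integer_, nrow(pc))
  if (nrow(pc) && nrow(rc)) {
    for (p in seq_len(nrow(pc))) {
      if (any(overlap[p, ] > 0)) assign_to[p] <- which.max(overlap[p, ])
    }
  }
  matched <- list(); fn <- list()
  for (r in seq_len(nrow(rc))) {
    need <- max(1, ceiling(min_overlap_frac * rc$voxels[r]))
    direct <- if (nrow(pc)) sum(overlap[, r]) else 0L
    detected <- direct >= need
    if (detected) {
      pids <- which(assign_to == r)
      union_vox <- sum(pc$voxels[pids])
      inter <- sum(overlap[pids, r])
      matched[[length(matched) + 1]] <- data.frame(
        ref_id = r, pred_ids = I(list(pids)),
        dsc = 2 * inter / (rc$voxels[r] + union_vox),
        ref_volume_mm3 = rc$volume_mm3[r],
        pred_volume_mm3 = union_vox * vv)
    } else {
      fn[[length(fn) + 1]] <- data.frame(ref_id = r,
                                         ref_volume_mm3 = rc$volume_mm3[r])
    }
  }
  fp_ids <- which(is.na(assign_to))
  structure(list(
    matched = if (length(matched)) do.call(rbind, matched) else
      data.frame(ref_id = integer(), pred_ids = I(list()), dsc = numeric(),
                 ref_volume_mm3 = numeric(), pred_volume_mm3 = numeric()),
    fn = if (length(fn)) do.call(rbind, fn) else
      data.frame(ref_id = integer(), ref_volume_mm3 = numeric()),
    fp = data.frame(pred_id = fp_ids, pred_volume_mm3 = pc$volume_mm3[fp_ids]),
    n_scans = 1L), class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> TP %d, FN %d, FP %d over %d scan(s)\n",
              nrow(x$matched), nrow(x$fn), nrow(x$fp), x$n_scans))
  invisible(x)
}

round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Detection sensitivity (recall) in percent
#'
#' `TP / (TP + FN) * 100`, rounded half away from zero to an integer for
#' reporting (set `rounded = FALSE` for the raw percentage).
#'
#' @param tp,fn True-positive and false-negative counts.
#' @param rounded Round to integer percent (default TRUE).
#' @return Percent in [0, 100].
#' @export
sensitivity <- function(tp, fn, rounded = TRUE) {
  if (tp + fn <= 0) stop("sensitivity undefined: tp + fn = 0")
  x <- tp / (tp + fn) * 100
  if (rounded) round_half_away(x) else x
}

#' Detection precision (positive predictive value) in percent
#'
#' `TP / (TP + FP) * 100`, same rounding convention as [sensitivity()].
#'
#' @param tp,fp True-positive and false-positive counts.
#' @param rounded Round to integer percent (default TRUE).
#' @return Percent in [0, 100].
#' @export
precision <- function(tp, fp, rounded = TRUE) {
  if (tp + fp <= 0) stop("precision undefined: tp + fp = 0")
  x <- tp / (tp + fp) * 100
  if (rounded) round_half_away(x) else x
}

#' F1 score from unrounded percentages
#'
#' `2 * (S * P) / (S + P) / 100` computed from the unrounded sensitivity and
#' precision percentages; reported to 2 decimals.
#'
#' @param sens_percent,prec_percent Unrounded percentages.
#' @param rounded Round to 2 decimals (default TRUE).
#' @return Unitless value in [0, 1].
#' @export
f1_score <- function(sens_percent, prec_percent, rounded = TRUE) {
  if (sens_percent + prec_percent <= 0) return(0)
  x <- 2 * (sens_percent * prec_percent) / (sens_percent + prec_percent) / 100
  if (rounded) round_half_away(x, 2) else x
}

#' Average false positives per scan
#'
#' `FP / n_scans`, reported to 2 decimals.
#'
#' @param fp False-positive count.
#' @param n_scans Number of scans (>= 1).
#' @param rounded Round to 2 decimals (default TRUE).
#' @return Rate >= 0.
#' @export
fps_per_scan <- function(fp, n_scans, rounded = TRUE) {
  if (n_scans < 1) stop("n_scans must be >= 1")
  x <- fp / n_scans
  if (rounded) round_half_away(x, 2) else x
}

#' Dice similarity coefficient between two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; symmetric, in [0, 1].
#'
#' @param a,b Binary `volume3d` masks on a common grid.
#' @return Unitless value in [0, 1].
#' @export
dsc <- function(a, b) {
  stop_if_grid_mismatch(a, b, "masks")
  av <- as_binary_values(a) > 0
  bv <- as_binary_values(b) > 0
  na <- sum(av); nb <- sum(bv)
  if (na + nb == 0) stop("DSC undefined: both masks are empty")
  2 * sum(av & bv) / (na + nb)
}

#' Pearson correlation of matched reference and predicted volumes
#'
#' @param ref_volumes,pred_volumes Numeric vectors (mm^3) of matched pairs,
#'   length >= 3, with nonzero variance in both.
#' @return Correlation coefficient r.
#' @export
pearson_volume_correlation <- function(ref_volumes, pred_volumes) {
  if (length(ref_volumes) != length(pred_volumes))
    stop("volume vectors differ in length")
  if (length(ref_volumes) < 3)
    stop("need at least 3 matched pairs")
  if (stats::sd(ref_volumes) == 0 || stats::sd(pred_volumes) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(ref_volumes, pred_volumes)
}

# pool a list of detection_result objects
pool_detections <- function(results) {
  if (inherits(results, "detection_result")) results <- list(results)
  list(matched = do.call(rbind, lapply(results, `[[`, "matched")),
       fn = do.call(rbind, lapply(results, `[[`, "fn")),
       fp = do.call(rbind, lapply(results, `[[`, "fp")),
       n_scans = sum(vapply(results, `[[`, 0L, "n_scans")))
}

#' Volume-binned cohort metrics report
#'
#' Computes sensitivity, precision, F1, FPs/scan, median pair DSC and the
#' Pearson correlation of matched volumes, overall and restricted to
#' reference components above each volume threshold. Within a stratum, TP
#' and FN are filtered by reference-component volume and FP counts by the
#' predicted component's own volume. Strata with no reference components
#' are absent from the report.
#'
#' @param results A `detection_result` or list of them (one per scan).
#' @param bins Numeric volume thresholds in mm^3 (default `c(30, 50, 100)`).
#' @return A data.frame with one row per stratum: `stratum`, `n_ref`, `tp`,
#'   `fn`, `fp`, `sensitivity_pct`, `precision_pct`, `f1`, `fps_per_scan`,
#'   `median_dsc`, `pearson_r`, `n_scans`.
#' @export
volume_binned_report <- function(results, bins = c(30, 50, 100)) {
  pooled <- pool_detections(results)
  strata <- c(list(list(label = "all", thr = -Inf)),
              lapply(bins, function(b)
                list(label = sprintf(">%g mm3", b), thr = b)))
  rows <- list()
  for (s in strata) {
    m <- pooled$matched[pooled$matched$ref_volume_mm3 > s$thr, , drop = FALSE]
    fn <- pooled$fn[pooled$fn$ref_volume_mm3 > s$thr, , drop = FALSE]
    fp <- pooled$fp[pooled$fp$pred_volume_mm3 > s$thr, , drop = FALSE]
    tp <- nrow(m)
    if (tp + nrow(fn) == 0) next  # empty stratum: absent, not zero
    sens_u <- sensitivity(tp, nrow(fn), rounded = FALSE)
    prec_u <- if (tp + nrow(fp) > 0) precision(tp, nrow(fp), rounded = FALSE)
      else NA_real_
    r <- if (tp >= 3 && stats::sd(m$ref_volume_mm3) > 0 &&
             stats::sd(m$pred_volume_mm3) > 0)
      pearson_volume_correlation(m$ref_volume_mm3, m$pred_volume_mm3)
      else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      stratum = s$label, n_ref = tp + nrow(fn), tp = tp, fn = nrow(fn),
      fp = nrow(fp),
      sensitivity_pct = round_half_away(sens_u),
      precision_pct = if (is.na(prec_u)) NA_real_ else round_half_away(prec_u),
      f1 = if (is.na(prec_u)) NA_real_ else
        round_half_away(f1_score(sens_u, prec_u, rounded = FALSE), 2),
      fps_per_scan = fps_per_scan(nrow(fp), pooled$n_scans),
      median_dsc = if (tp > 0) stats::median(m$dsc) else NA_real_,
      pearson_r = r, n_scans = pooled$n_scans)
  }
  do.call(rbind, rows)
}
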