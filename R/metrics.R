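# Evaluation metrics: 3D intersection-point deviation (pos), shortest
# distance to the true axial plane (pos2Ax, the clinically dominant error
# since it shifts the visualized level), and per-plane angular deviations.

#' Frame-to-frame error metrics
#'
#' `pos` is the Euclidean distance between the predicted and true
#' intersection points; `pos2ax` is the absolute projection of that offset
#' onto the *true* axial normal, i.e. the shortest distance from the
#' predicted point to the true axial plane (so `pos2ax <= pos` always). The
#' three angular deviations are `acos(|n_hat . n|)` in degrees —
#' sign-invariant, folded to \[0, 90\], because normal signs are a
#' convention, not a measurement.
#'
#' @param predicted,truth [plane_frame()]s.
#' @return An object of class `frame_errors` with fields `pos_mm`,
#'   `pos2ax_mm`, `ang_sag_deg`, `ang_ax_deg`, `ang_cor_deg`.
#' @export
frame_errors <- function(predicted, truth) {
  stopifnot(inherits(predicted, "plane_frame"), inherits(truth, "plane_frame"))
  dp <- predicted$intersection_mm - truth$intersection_mm
  ang <- function(a, b) rad2deg(acos(min(1, max(0, abs(sum(a * b))))))
  structure(list(pos_mm = sqrt(sum(dp^2)),
                 pos2ax_mm = abs(sum(dp * truth$n_ax)),
                 ang_sag_deg = ang(predicted$n_sag, truth$n_sag),
                 ang_ax_deg = ang(predicted$n_ax, truth$n_ax),
                 ang_cor_deg = ang(predicted$n_cor, truth$n_cor)),
            class = "frame_errors")
}

#' @export
print.frame_errors <- function(x, ...) {
  cat(sprintf("<frame_errors> pos %.3f mm, pos2Ax %.3f mm; sag %.2f, ax %.2f, cor %.2f deg\n",
              x$pos_mm, x$pos2ax_mm, x$ang_sag_deg, x$ang_ax_deg, x$ang_cor_deg))
  invisible(x)
}

errors_to_row <- function(e) {
  data.frame(pos_mm = e$pos_mm, pos2ax_mm = e$pos2ax_mm,
             ang_sag_deg = e$ang_sag_deg, ang_ax_deg = e$ang_ax_deg,
             ang_cor_deg = e$ang_cor_deg)
}

#' Summarize per-case frame errors
#'
#' Reports, per metric, the median over all cases, the standard deviation
#' over all cases, the standard deviation over per-group medians (the
#' cross-validation-fold style summary; 0 with `sd_groups_defined = FALSE`
#' when fewer than two groups are present), and the maximum (for
#' localization-style audits).
#'
#' @param errors a list of [frame_errors()] or a data.frame of their fields.
#' @param grouping optional vector of group / fold labels, one per case.
#' @return An object of class `error_summary`: a data.frame `stats` with one
#'   row per metric, plus `n_cases`, `n_groups`, `sd_groups_defined`.
#' @export
summarize_errors <- function(errors, grouping = NULL) {
  if (is.data.frame(errors)) df <- errors
  else {
    if (length(errors) == 0L) stop("empty input: no error cases to summarize")
    df <- do.call(rbind, lapply(errors, errors_to_row))
  }
  if (nrow(df) == 0L) stop("empty input: no error cases to summarize")
  metrics <- c("pos_mm", "pos2ax_mm", "ang_sag_deg", "ang_ax_deg", "ang_cor_deg")
  metrics <- intersect(metrics, names(df))
  if (is.null(grouping)) grouping <- rep(1L, nrow(df))
  stopifnot(length(grouping) == nrow(df))
  groups <- unique(grouping)
  sd_groups_defined <- length(groups) >= 2L
  stats <- do.call(rbind, lapply(metrics, function(m) {
    v <- df[[m]]
    gm <- vapply(groups, function(g) median(v[grouping == g]), 0)
    data.frame(metric = m,
               median = median(v),
               sd = if (length(v) > 1L) sd(v) else 0,
               sd_group_medians = if (sd_groups_defined) sd(gm) else 0,
               max = max(v))
  }))
  structure(list(stats = stats, n_cases = nrow(df), n_groups = length(groups),
                 sd_groups_defined = sd_groups_defined),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("<error_summary> %d case(s), %d group(s)%s\n", x$n_cases, x$n_groups,
              if (!x$sd_groups_defined) "  [group sd undefined, reported as 0]" else ""))
  print(x$stats, row.names = FALSE, digits = 4)
  invisible(x)
}

# optimal prediction<->truth pairing by nearest intersection point; for the
# bilateral 2x2 case this is the exhaustive Hungarian assignment
match_detections <- function(pred_points, truth_points) {
  np <- length(pred_points); nt <- length(truth_points)
  cost <- matrix(0, np, nt)
  for (i in seq_len(np)) for (j in seq_len(nt))
    cost[i, j] <- sqrt(sum((pred_points[[i]] - truth_points[[j]])^2))
  k <- min(np, nt)
  perms <- if (nt == 1L) list(1L) else list(c(1L, 2L), c(2L, 1L))
  if (np == 1L && nt == 2L) perms <- list(1L, 2L)
  best <- NULL; best_cost <- Inf
  for (pm in perms) {
    idx <- cbind(seq_len(min(np, length(pm))), pm[seq_len(min(np, length(pm)))])
    cc <- sum(cost[idx])
    if (cc < best_cost) { best_cost <- cc; best <- pm }
  }
  # rows: prediction index, truth index
  cbind(pred = seq_len(min(np, length(best))), truth = best[seq_len(min(np, length(best)))])
}

#' Run the full pipeline over phantom samples and tabulate errors
#'
#' For each sample: localize with `k = ` the sample's ankle count, crop an
#' ROI per detection, estimate the frame, match predictions to ground truths
#' by nearest intersection point (exhaustive assignment on the 2x2 cost),
#' and compute [frame_errors()]. Unmatched ankles are counted and reported,
#' never silently dropped.
#'
#' @param samples list of [generate_phantom()] results.
#' @param predictor_for,segmenter_for functions taking a sample and returning
#'   the stage-1 patch predictor / stage-2 segmenter to use (defaults: exact
#'   oracles). Pass closures over trained networks to evaluate learning.
#' @param config a [pipeline_config()]; controls patch/stride/crop sizes.
#' @param grouping optional per-sample group labels for [summarize_errors()].
#' @return list with `per_case` (data.frame: sample, ankle, laterality_true,
#'   laterality_pred, metrics, flags), `summary` (an `error_summary`),
#'   `n_unmatched`.
#' @export
evaluate_run <- function(samples,
                         predictor_for = function(s) oracle_sphere_predictor(s),
                         segmenter_for = function(s) oracle_plane_segmenter(s),
                         config = pipeline_config(),
                         grouping = NULL) {
  if (length(samples) == 0L) stop("empty input: no samples to evaluate")
  rows <- list()
  n_unmatched <- 0L
  for (si in seq_along(samples)) {
    s <- samples[[si]]
    n_ank <- length(s$frames)
    det <- localize(s$volume, predictor_for(s), n_ankles = n_ank,
                    patch_size = config$patch_size, stride = config$stride,
                    weight_floor = config$weight_floor)
    ests <- lapply(det, function(d) {
      roi <- crop_roi(s$volume, d$center_mm, config$crop_size)
      estimate_planes(roi, segmenter_for(s), min_voxels = config$min_voxels)
    })
    mt <- match_detections(lapply(ests, function(e) e$frame$intersection_mm),
                           lapply(s$frames, function(f) f$intersection_mm))
    n_unmatched <- n_unmatched + (n_ank - nrow(mt)) + (length(ests) - nrow(mt))
    for (r in seq_len(nrow(mt))) {
      est <- ests[[mt[r, "pred"]]]
      truth <- s$frames[[mt[r, "truth"]]]
      e <- frame_errors(est$frame, truth)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(sample = si, ankle = mt[r, "truth"],
                   laterality_true = s$lateralities[mt[r, "truth"]],
                   laterality_pred = classify_laterality(est$frame)),
        errors_to_row(e),
        data.frame(degenerate = any(est$degenerate_classes)))
    }
  }
  per_case <- do.call(rbind, rows)
  grp <- if (is.null(grouping)) NULL else grouping[per_case$sample]
  list(per_case = per_case,
       summary = summarize_errors(per_case[, c("pos_mm", "pos2ax_mm", "ang_sag_deg",
                                               "ang_ax_deg", "ang_cor_deg")], grp),
       n_unmatched = n_unmatched)
}
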