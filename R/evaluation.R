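#' Per-frame center error
#'
#' Euclidean distance in pixels between predicted and ground-truth box
#' centres; the centre of an `(x, y, w, h)` box is `(x + w/2, y + h/2)`.
#'
#' @param pred,gt data.frames of boxes `(x, y, w, h)` with equal row counts
#' @return list with `delta` (per-frame distances) and `mean`
#' @export
center_error <- function(pred, gt) {
  if (nrow(pred) != nrow(gt)) {
    stop("center_error: trajectory length mismatch", call. = FALSE)
  }
  dx <- (pred$x + pred$w / 2) - (gt$x + gt$w / 2)
  dy <- (pred$y + pred$h / 2) - (gt$y + gt$h / 2)
  delta <- sqrt(dx^2 + dy^2)
  list(delta = delta, mean = mean(delta))
}

#' Per-frame bounding-box overlap
#'
#' Intersection-over-union of axis-aligned rectangles with continuous
#' areas. A zero-area predicted or ground-truth box yields overlap 0 for
#' that frame (flagged via attribute `degenerate`).
#'
#' @inheritParams center_error
#' @return numeric vector of per-frame overlaps in \[0, 1\]
#' @export
overlap_series <- function(pred, gt) {
  if (nrow(pred) != nrow(gt)) {
    stop("overlap_series: trajectory length mismatch", call. = FALSE)
  }
  ix <- pmax(0, pmin(pred$x + pred$w, gt$x + gt$w) - pmax(pred$x, gt$x))
  iy <- pmax(0, pmin(pred$y + pred$h, gt$y + gt$h) - pmax(pred$y, gt$y))
  inter <- ix * iy
  union <- pred$w * pred$h + gt$w * gt$h - inter
  degen <- pred$w * pred$h <= 0 | gt$w * gt$h <= 0
  phi <- ifelse(degen | union <= 0, 0, inter / union)
  attr(phi, "degenerate") <- which(degen)
  phi
}

#' Precision curve over distance thresholds
#'
#' Fraction of frames whose centre error is within each threshold
#' (non-decreasing in the threshold).
#'
#' @param delta per-frame centre errors
#' @param thresholds sorted distance thresholds (default 0..50 px step 1)
#' @return data.frame with `threshold` and `precision`
#' @export
precision_curve <- function(delta, thresholds = seq(0, 50, by = 1)) {
  data.frame(threshold = thresholds,
             precision = vapply(thresholds, function(th) mean(delta <= th), numeric(1)))
}

#' Success curve over overlap thresholds
#'
#' Fraction of frames whose overlap exceeds each threshold (non-increasing
#' in the threshold).
#'
#' @param phi per-frame overlaps
#' @param thresholds sorted overlap thresholds (default 0..1 step 0.05)
#' @return data.frame with `threshold` and `success`
#' @export
success_curve <- function(phi, thresholds = seq(0, 1, by = 0.05)) {
  data.frame(threshold = thresholds,
             success = vapply(thresholds, function(th) mean(phi > th), numeric(1)))
}

#' Area under the success curve
#'
#' Computed as the mean per-frame overlap, which equals the area under the
#' success plot; the trapezoid-integrated curve agrees within the threshold
#' discretization.
#'
#' @param phi per-frame overlaps
#' @return the AUC score in \[0, 1\]
#' @export
auc_score <- function(phi) mean(phi)

.metric_curves <- function(pred, gt) {
  ce <- center_error(pred, gt)
  phi <- overlap_series(pred, gt)
  list(delta = ce$delta, mean_delta = ce$mean, phi = as.numeric(phi),
       precision = precision_curve(ce$delta),
       success = success_curve(phi),
       auc = auc_score(phi))
}

#' One-pass evaluation (OPE)
#'
#' Runs the tracker once over the whole sequence, initialized with the
#' ground truth of the first frame, and computes all metrics.
#'
#' @param tracker function `(frames, init_box)` returning a data.frame of
#'   predicted boxes, one row per frame
#' @param sequence list with `frames` and `gt` (as from
#'   [load_otb_sequence()] or [generate_synthetic_video()])
#' @return metric list: per-frame `delta` and `phi`, `mean_delta`,
#'   `precision`, `success` curves and `auc`
#' @export
run_ope <- function(tracker, sequence) {
  pred <- tracker(sequence$frames, as.numeric(sequence$gt[1, c("x", "y", "w", "h")]))
  .metric_curves(pred[, c("x", "y", "w", "h")], sequence$gt)
}

#' Temporal robustness evaluation (TRE)
#'
#' Splits the sequence into `n_segments` suffixes with evenly spaced start
#' frames; the tracker is re-initialized with the ground truth at each start
#' and run to the end. Metrics are averaged over runs. `n_segments = 1`
#' reduces to OPE.
#'
#' @inheritParams run_ope
#' @param n_segments number of segment starts (default 20)
#' @return list with `runs` (per-segment metric lists), `auc` (mean),
#'   `mean_delta` (mean), and `starts`
#' @export
run_tre <- function(tracker, sequence, n_segments = 20) {
  T_len <- length(sequence$frames)
  starts <- unique(floor((seq_len(n_segments) - 1) * T_len / n_segments) + 1)
  starts <- starts[starts < T_len]  # a segment needs at least 2 frames
  runs <- lapply(starts, function(s) {
    sub <- list(frames = sequence$frames[s:T_len], gt = sequence$gt[s:T_len, ])
    run_ope(tracker, sub)
  })
  list(runs = runs,
       auc = mean(vapply(runs, `[[`, numeric(1), "auc")),
       mean_delta = mean(vapply(runs, `[[`, numeric(1), "mean_delta")),
       starts = starts)
}

#' Spatial robustness evaluation (SRE)
#'
#' Perturbs the first-frame initialization: 8 shifts of 10% of the box size
#' (4 cardinal + 4 diagonal directions) and 4 centre-preserving scalings
#' (x0.8, x0.9, x1.1, x1.2), 12 variants in total. Metrics are averaged
#' over the variant runs.
#'
#' @inheritParams run_ope
#' @param variants optional data.frame `(dx, dy, scale)` overriding the
#'   default 12 perturbations (in fractions of box size)
#' @return list with `runs`, `auc` (mean), `mean_delta` (mean), `variants`
#' @export
run_sre <- function(tracker, sequence, variants = NULL) {
  if (is.null(variants)) {
    d <- c(-0.1, 0, 0.1)
    shifts <- expand.grid(dx = d, dy = d)
    shifts <- shifts[!(shifts$dx == 0 & shifts$dy == 0), ]
    variants <- rbind(data.frame(dx = shifts$dx, dy = shifts$dy, scale = 1),
                      data.frame(dx = 0, dy = 0, scale = c(0.8, 0.9, 1.1, 1.2)))
  }
  gt1 <- as.numeric(sequence$gt[1, c("x", "y", "w", "h")])
  runs <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    w <- gt1[3] * v$scale; h <- gt1[4] * v$scale
    cx <- gt1[1] + gt1[3] / 2 + v$dx * gt1[3]
    cy <- gt1[2] + gt1[4] / 2 + v$dy * gt1[4]
    init <- c(cx - w / 2, cy - h / 2, w, h)
    pred <- tracker(sequence$frames, init)
    .metric_curves(pred[, c("x", "y", "w", "h")], sequence$gt)
  })
  list(runs = runs,
       auc = mean(vapply(runs, `[[`, numeric(1), "auc")),
       mean_delta = mean(vapply(runs, `[[`, numeric(1), "mean_delta")),
       variants = variants)
}

#' Export metrics to CSV and JSON
#'
#' Writes the per-frame series (`delta`, `phi`) as CSV and the summary
#' scores (`auc`, `mean_delta`) plus curves as JSON.
#'
#' @param metrics result of [run_ope()]
#' @param prefix output path prefix (writes `<prefix>_frames.csv` and
#'   `<prefix>_summary.json`)
#' @return invisibly, the two file paths
#' @export
export_metrics <- function(metrics, prefix) {
  csv <- paste0(prefix, "_frames.csv")
  js <- paste0(prefix, "_summary.json")
  utils::write.csv(data.frame(frame = seq_along(metrics$delta),
                              center_error = metrics$delta,
                              overlap = metrics$phi),
                   csv, row.names = FALSE)
  jsonlite::write_json(list(auc = metrics$auc, mean_center_error = metrics$mean_delta,
                            precision = metrics$precision, success = metrics$success),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
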