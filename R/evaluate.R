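#' Match detection events to ground-truth annotations
#'
#' Per channel (and subject, when present), each ground-truth mark owns the
#' interval `[t_peak - window_s/2, t_peak + window_s/2]`. A mark whose window
#' contains at least one event is a single true positive no matter how many
#' events fall inside it — an SD that triggers multiple probability peaks is
#' still one SD — and marks whose windows contain no event are false
#' negatives. Windows are scored independently, so one long event may
#' support two adjacent marks. Events overlapping no window are false
#' positives. For diagnostics, each event is additionally attributed to its
#' nearest-by-peak overlapping mark in the `assignment` table.
#'
#' @param events event data frame from [threshold_events] /
#'   [detect_recording].
#' @param ann an [sd_annotations] ground-truth set.
#' @param window_s width of the positive window around each mark (default
#'   400 s, i.e. +/- 200 s).
#' @return list with counts `TP`, `FP`, `FN` and `assignment`, a data frame
#'   mapping each event to its mark index (NA for false positives).
#' @export
match_detections <- function(events, ann, window_s = 400) {
  events <- as.data.frame(events)
  ann <- as.data.frame(ann)
  key <- function(df) {
    if ("subject" %in% names(df) && "subject" %in% names(events) && "subject" %in% names(ann))
      paste(df$subject, df$channel, sep = "\r") else as.character(df$channel)
  }
  if (nrow(events) > 0 && nrow(ann) > 0 &&
      length(intersect(unique(events$channel), unique(ann$channel))) == 0)
    stop("channel labels of events and annotations do not match")
  half <- window_s / 2
  ek <- if (nrow(events)) key(events) else character(0)
  ak <- if (nrow(ann)) key(ann) else character(0)
  assigned_mark <- rep(NA_integer_, nrow(events))
  mark_hit <- rep(FALSE, nrow(ann))
  for (e in seq_len(nrow(events))) {
    cand <- which(ak == ek[e] &
                    events$t_start[e] <= ann$t_peak_s + half &
                    events$t_end[e] >= ann$t_peak_s - half)
    if (length(cand) == 0) next
    nearest <- cand[which.min(abs(events$t_peak[e] - ann$t_peak_s[cand]))]
    assigned_mark[e] <- nearest
    mark_hit[cand] <- TRUE
  }
  list(TP = sum(mark_hit), FP = sum(is.na(assigned_mark)), FN = sum(!mark_hit),
       assignment = data.frame(event = seq_len(nrow(events)), mark = assigned_mark))
}

#' Detection performance metrics
#'
#' Computes sensitivity (recall) `TP/(TP+FN)`, precision `TP/(TP+FP)`,
#' `F1 = 2 * precision * recall / (precision + recall)`, the objective
#' function `OBJ = TP^2 - 2*FP^2` (false positives carry twice the penalty;
#' reported both raw and in units of 1e5), and the false-positive rate per
#' 24 h of recording, `FP / (recording_hours/24)`. `recording_hours` is the
#' total of channel-hours scored (e.g. 24 h x 6 channels = 144 h for one
#' day of strip recording). Zero denominators yield 0 by convention.
#' Specificity is not reported: continuous data define no true-negative
#' unit.
#'
#' @param tp,fp,fn non-negative counts.
#' @param recording_hours total scored recording time in hours.
#' @return an `sd_eval_report` list.
#' @export
sd_metrics <- function(tp, fp, fn, recording_hours) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative")
  if (recording_hours <= 0) stop("recording_hours must be positive")
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  obj <- tp^2 - 2 * fp^2
  structure(list(TP = tp, FP = fp, FN = fn, recording_hours = recording_hours,
                 sensitivity = sens, precision = prec, f1 = f1,
                 obj = obj, obj_1e5 = obj / 1e5,
                 fp_per_day = fp / (recording_hours / 24),
                 adjusted_fp = NULL, adjusted_fp_per_day = NULL),
            class = "sd_eval_report")
}

#' @export
print.sd_eval_report <- function(x, ...) {
  cat(sprintf("<sd_eval_report> TP=%d FP=%d FN=%d over %.0f h\n", x$TP, x$FP, x$FN,
              x$recording_hours))
  cat(sprintf("  sensitivity %.3f | precision %.3f | F1 %.3f | OBJ %.1f x 1e5 | %.1f FP/day\n",
              x$sensitivity, x$precision, x$f1, x$obj_1e5, x$fp_per_day))
  if (!is.null(x$adjusted_fp))
    cat(sprintf("  adjudicated: %d FP remain (%.1f/day)\n", x$adjusted_fp,
                x$adjusted_fp_per_day))
  invisible(x)
}

#' Fold post-hoc adjudication into a report
#'
#' Expert re-review of detections initially counted as false positives may
#' reclassify some as real (possible/probable/definite) SDs. This reduces
#' the adjusted FP count while the original counts are retained.
#'
#' @param report an `sd_eval_report`.
#' @param adjudicated_real number of original FPs judged to be real SDs
#'   (between 0 and `report$FP`).
#' @return the report with `adjusted_fp` and `adjusted_fp_per_day` filled in.
#' @export
apply_adjudication <- function(report, adjudicated_real) {
  stopifnot(inherits(report, "sd_eval_report"))
  if (adjudicated_real < 0 || adjudicated_real > report$FP)
    stop("adjudicated_real must be between 0 and FP")
  report$adjusted_fp <- report$FP - adjudicated_real
  report$adjusted_fp_per_day <- report$adjusted_fp / (report$recording_hours / 24)
  report
}

#' Evaluate events against annotations in one call
#'
#' [match_detections] followed by [sd_metrics].
#' @inheritParams match_detections
#' @inheritParams sd_metrics
#' @param adjudicated_real optional count for [apply_adjudication].
#' @return an `sd_eval_report`.
#' @export
evaluate_detections <- function(events, ann, recording_hours, window_s = 400,
                                adjudicated_real = NULL) {
  m <- match_detections(events, ann, window_s)
  rep <- sd_metrics(m$TP, m$FP, m$FN, recording_hours)
  if (!is.null(adjudicated_real)) rep <- apply_adjudication(rep, adjudicated_real)
  rep
}

#' Sweep the detection-threshold surface
#'
#' Re-thresholds the stored probability traces over the full cross-product
#' of `theta_p_grid` x `theta_d_grid` and scores each combination against
#' the annotations, producing the table behind an F1 surface plot.
#'
#' @param traces list of `sd_probability_trace` objects (all channels, all
#'   subjects).
#' @param ann pooled [sd_annotations].
#' @param theta_p_grid,theta_d_grid numeric grids.
#' @param recording_hours total channel-hours represented by `traces`.
#' @param window_s matching window (default 400 s).
#' @return data frame, one row per (theta_p, theta_d), sorted by F1
#'   descending.
#' @export
threshold_sweep <- function(traces, ann, theta_p_grid, theta_d_grid,
                            recording_hours, window_s = 400) {
  stopifnot(length(theta_p_grid) > 0, length(theta_d_grid) > 0)
  combos <- expand.grid(theta_p = theta_p_grid, theta_d = theta_d_grid,
                        KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(r) {
    params <- detection_params(combos$theta_p[r], combos$theta_d[r])
    events <- do.call(rbind, lapply(traces, threshold_events, params = params))
    rep <- evaluate_detections(events, ann, recording_hours, window_s)
    data.frame(theta_p = combos$theta_p[r], theta_d = combos$theta_d[r],
               TP = rep$TP, FP = rep$FP, FN = rep$FN,
               sensitivity = rep$sensitivity, precision = rep$precision,
               f1 = rep$f1, obj = rep$obj, fp_per_day = rep$fp_per_day)
  })
  out <- do.call(rbind, rows)
  out[order(-out$f1), , drop = FALSE]
}
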