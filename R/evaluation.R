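# Segment tables may come as start/end or start_beat/end_beat columns.
normalize_segments <- function(x, what = "segments") {
  if (is.null(x)) return(tibble(start = integer(), end = integer()))
  if (!is.data.frame(x)) abort(sprintf("`%s` must be a data frame.", what))
  nm <- names(x)
  s <- if ("start" %in% nm) x$start else if ("start_beat" %in% nm)
    x$start_beat else abort(sprintf("`%s` needs a start/start_beat column.", what))
  e <- if ("end" %in% nm) x$end else if ("end_beat" %in% nm)
    x$end_beat else abort(sprintf("`%s` needs an end/end_beat column.", what))
  if (any(e <= s)) abort(sprintf("`%s` must be non-empty half-open intervals.",
                                 what))
  arrange(tibble(start = as.integer(s), end = as.integer(e)), .data$start)
}

#' Score one labelled PAF segment against the detections
#'
#' Implements the per-segment PAF-score: let `L` be the labelled PAF segment
#' and `D` the union of detected segments overlapping it (half-open beat
#' intervals). If `D` is a single detected run whose onset and offset each
#' differ from `L`'s by fewer than `tol_beats` beats, the detection is
#' considered consistent with the annotation and scores the maximum 1.
#' Otherwise the score is the intersection-over-union `|L n D| / |L u D|`
#' counted in beats; no overlap scores 0. Fragmented detections never take
#' the tolerance shortcut.
#'
#' @param label One-row data frame (or list) with `start`/`end` (or
#'   `start_beat`/`end_beat`) of the labelled PAF segment.
#' @param detections Data frame of detected segments on the same beat axis.
#' @param tol_beats Onset/offset tolerance in beats (default 3, applied
#'   strictly: differences must be `< tol_beats`).
#' @return A number in `[0, 1]`.
#' @examples
#' segment_score(data.frame(start = 100, end = 200),
#'               data.frame(start = 102, end = 199))
#' @export
segment_score <- function(label, detections, tol_beats = 3L) {
  L <- normalize_segments(as.data.frame(label), "label")[1, ]
  D <- normalize_segments(detections, "detections")
  ov <- D[overlap_beats(L$start, L$end, D$start, D$end) > 0L, ]
  if (nrow(ov) == 0L) return(0)

  if (nrow(ov) == 1L &&
      abs(ov$start - L$start) < tol_beats &&
      abs(ov$end - L$end) < tol_beats) {
    return(1)
  }
  merged <- merge_intervals(ov$start, ov$end)
  inter <- sum(overlap_beats(L$start, L$end, merged$start, merged$end))
  # |L u D| = |L| + |D| - |L n D| over the overlapping detections
  union <- (L$end - L$start) + sum(merged$end - merged$start) - inter
  inter / union
}

#' Average PAF-score of a recording
#'
#' The mean of [segment_score()] over all labelled PAF segments; labelled
#' segments with no overlapping detection contribute 0.
#'
#' @param labels Data frame of labelled PAF segments (`start`/`end` beat
#'   columns).
#' @inheritParams segment_score
#' @return A number in `[0, 1]`, or `NA` when there are no labelled segments.
#' @export
recording_score <- function(labels, detections, tol_beats = 3L) {
  L <- normalize_segments(labels, "labels")
  if (nrow(L) == 0L) return(NA_real_)
  mean(map_dbl(seq_len(nrow(L)),
               function(i) segment_score(L[i, ], detections, tol_beats)))
}

#' Error segments: detections containing no PAF-labelled beat
#'
#' @inheritParams recording_score
#' @return Integer count of detected segments with zero beats inside any
#'   labelled PAF segment.
#' @export
count_error_segments <- function(labels, detections) {
  L <- normalize_segments(labels, "labels")
  D <- normalize_segments(detections, "detections")
  if (nrow(D) == 0L) return(0L)
  sum(map_int(seq_len(nrow(D)), function(i) {
    as.integer(sum(overlap_beats(D$start[i], D$end[i], L$start, L$end)) == 0L)
  }))
}

#' Missed segments: labelled PAF segments with no detected beat
#'
#' @inheritParams recording_score
#' @return Integer count of labelled segments with zero overlapping detected
#'   beats.
#' @export
count_missed_segments <- function(labels, detections) {
  L <- normalize_segments(labels, "labels")
  D <- normalize_segments(detections, "detections")
  if (nrow(L) == 0L) return(0L)
  sum(map_int(seq_len(nrow(L)), function(i) {
    as.integer(sum(overlap_beats(L$start[i], L$end[i], D$start, D$end)) == 0L)
  }))
}

#' Beat-level sensitivity, specificity and accuracy
#'
#' Every beat on the axis `1..total_beats` is labelled AF when inside a
#' labelled segment and detected-AF when inside a detected segment;
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' accuracy = (TP+TN)/total. A metric whose class has no beats is reported
#' `NA` rather than 0/0.
#'
#' @inheritParams recording_score
#' @param total_beats Number of beats on the common axis.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `accuracy`.
#' @export
beat_metrics <- function(labels, detections, total_beats) {
  total_beats <- assert_count(total_beats, "total_beats", min = 1L)
  L <- normalize_segments(labels, "labels")
  D <- normalize_segments(detections, "detections")
  lab <- logical(total_beats)
  for (i in seq_len(nrow(L)))
    lab[max(1L, L$start[i]):min(total_beats, L$end[i] - 1L)] <- TRUE
  det <- logical(total_beats)
  for (i in seq_len(nrow(D)))
    det[max(1L, D$start[i]):min(total_beats, D$end[i] - 1L)] <- TRUE
  tp <- sum(lab & det); fn <- sum(lab & !det)
  tn <- sum(!lab & !det); fp <- sum(!lab & det)
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / total_beats)
}

#' Full detection evaluation report
#'
#' Bundles the per-segment PAF-scores, their average, the error and missed
#' segment counts and the beat-level confusion metrics into one object with
#' [tidy()] / [glance()] methods.
#'
#' @inheritParams beat_metrics
#' @inheritParams segment_score
#' @return A `paf_eval` object.
#' @examples
#' labels <- data.frame(start = 101, end = 181)
#' dets <- data.frame(start = 99, end = 183)
#' glance(evaluate_detection(labels, dets, total_beats = 280))
#' @export
evaluate_detection <- function(labels, detections, total_beats,
                               tol_beats = 3L) {
  L <- normalize_segments(labels, "labels")
  D <- normalize_segments(detections, "detections")
  scores <- if (nrow(L)) {
    map_dbl(seq_len(nrow(L)), function(i) segment_score(L[i, ], D, tol_beats))
  } else numeric(0)
  structure(
    list(labels = L, detections = D,
         per_segment = mutate(L, score = scores),
         average_score = if (length(scores)) mean(scores) else NA_real_,
         error_segments = count_error_segments(L, D),
         missed_segments = count_missed_segments(L, D),
         beats = beat_metrics(L, D, total_beats),
         total_beats = total_beats),
    class = "paf_eval")
}

#' @export
print.paf_eval <- function(x, ...) {
  cat(sprintf(
    "<paf_eval> %d labelled / %d detected segment(s)\n",
    nrow(x$labels), nrow(x$detections)))
  cat(sprintf("  average PAF-score %.3f | error %d | missed %d\n",
              x$average_score, x$error_segments, x$missed_segments))
  b <- x$beats
  cat(sprintf("  beat-level Se %.4f  Sp %.4f  Acc %.4f\n",
              b$sensitivity, b$specificity, b$accuracy))
  invisible(x)
}

#' @describeIn evaluate_detection Per-labelled-segment scores.
#' @param x A `paf_eval`.
#' @param ... Unused.
#' @method tidy paf_eval
#' @export
tidy.paf_eval <- function(x, ...) as_tibble(x$per_segment)

#' @describeIn evaluate_detection One-row summary of all metrics.
#' @method glance paf_eval
#' @export
glance.paf_eval <- function(x, ...) {
  dplyr::bind_cols(
    tibble(n_labeled = nrow(x$labels), n_detected = nrow(x$detections),
           average_score = x$average_score,
           error_segments = x$error_segments,
           missed_segments = x$missed_segments),
    x$beats)
}
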