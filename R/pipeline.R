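#' Pipeline configuration
#'
#' Collects every tunable of the detection pipeline with its default. The
#' configuration used for a run is embedded in the run's result object, so
#' outputs are reproducible from the result alone.
#'
#' @param threshold Rc screening threshold (default 0.05, the calibrated
#'   operating point; see [calibrate_rc_threshold()]).
#' @param std_mode `"population"` or `"sample"` standard deviation in Rc.
#' @param merge_gap_beats Candidate-run merge gap (default 6).
#' @param single_pb_max_run Single-PB run-length bound (default 10).
#' @param geminy_min_count Geminal pattern minimum count (default 3).
#' @param baseline_win1_ms,baseline_win2_ms Median-filter windows (ms).
#' @param sqa_window_s,sqa_flat_mv,sqa_sat_frac,sqa_peak_mad_factor
#'   Signal-quality gating parameters, see [assess_quality()].
#' @param qrs_refine_radius_ms QRS refinement radius (ms).
#' @param seed Optional integer seed (tie-breaking in clustering).
#' @return A named list of class `paf_config`.
#' @export
paf_config <- function(threshold = 0.05,
                       std_mode = c("population", "sample"),
                       merge_gap_beats = 6L,
                       single_pb_max_run = 10L,
                       geminy_min_count = 3L,
                       baseline_win1_ms = 200,
                       baseline_win2_ms = 600,
                       sqa_window_s = 2,
                       sqa_flat_mv = 0.05,
                       sqa_sat_frac = 0.2,
                       sqa_peak_mad_factor = 4,
                       qrs_refine_radius_ms = 50,
                       seed = NULL) {
  std_mode <- match.arg(std_mode)
  assert_positive_scalar(threshold, "threshold")
  cfg <- list(
    threshold = threshold, std_mode = std_mode,
    merge_gap_beats = assert_count(merge_gap_beats, "merge_gap_beats", 0L),
    single_pb_max_run = assert_count(single_pb_max_run, "single_pb_max_run"),
    geminy_min_count = assert_count(geminy_min_count, "geminy_min_count"),
    baseline_win1_ms = baseline_win1_ms,
    baseline_win2_ms = baseline_win2_ms,
    sqa_window_s = sqa_window_s, sqa_flat_mv = sqa_flat_mv,
    sqa_sat_frac = sqa_sat_frac,
    sqa_peak_mad_factor = sqa_peak_mad_factor,
    qrs_refine_radius_ms = qrs_refine_radius_ms,
    seed = seed)
  class(cfg) <- "paf_config"
  cfg
}

#' @export
print.paf_config <- function(x, ...) {
  cat("<paf_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-22s %s\n", k,
                if (is.null(v)) "NULL" else format(v)))
  }
  invisible(x)
}

#' Detect paroxysmal-AF segments
#'
#' End-to-end detection: (waveform mode only) baseline removal, signal
#' quality gating, QRS detection and refinement, RR derivation; then the
#' rhythm-change screen ([rc_series()], [candidate_segments()]) and the
#' premature-beat rejection cascade ([classify_candidate()]) on every
#' candidate. Candidates classified AF become detected PAF segments with
#' the 6-interval window span of the flagged run split evenly across both
#' edges (onset and offset shifted 3 beats late, since an Rc value describes
#' the six intervals after its beat and boundary windows flag on partial
#' overlap). All rejected candidates are kept in the verdict log.
#'
#' @param input One of: a `paf_recording`, a per-beat data frame with an
#'   `rr_s` column, a bare numeric RR vector (RR mode); or a `paf_ecg`, a
#'   `wfdb_record`, or `list(signal =, fs =)` (waveform mode).
#' @param config A [paf_config()].
#' @return A `paf_detection`: list with `detections` (tibble `start_beat`,
#'   `end_beat`, half-open), `verdicts` (one row per candidate with its
#'   cascade outcome), `rc` (the `tbl_rc` series), `n_beats`, `beats` and
#'   `config`.
#' @examples
#' rec <- gen_recording(list(
#'   list(spec = rhythm_spec("NSR", 100), label = "N"),
#'   list(spec = rhythm_spec("AF", 80), label = "AFIB"),
#'   list(spec = rhythm_spec("NSR", 100), label = "N")), seed = 7)
#' det <- detect_paf(rec)
#' tidy(det)
#' @export
detect_paf <- function(input, config = paf_config()) {
  stopifnot(inherits(config, "paf_config"))

  beats <- resolve_input(input, config)
  n_beats <- nrow(beats)
  rc <- rc_series(beats, threshold = config$threshold,
                  std_mode = config$std_mode)
  cands <- candidate_segments(rc, merge_gap_beats = config$merge_gap_beats)

  rr_full <- rep(NA_real_, n_beats)
  rr_full[beats$beat] <- beats$rr_s
  if ("contiguous" %in% names(beats)) {
    contig <- rep(FALSE, n_beats)
    contig[beats$beat] <- !is.na(beats$contiguous) & beats$contiguous
    rr_full[!contig & !is.na(rr_full)] <- NA_real_
  }

  verdicts <- map(seq_len(nrow(cands)), function(i) {
    v <- classify_candidate(cands[i, ], rr_full,
                            threshold = config$threshold,
                            single_pb_max_run = config$single_pb_max_run,
                            geminy_min_count = config$geminy_min_count,
                            std_mode = config$std_mode,
                            seed = config$seed)
    tibble(start_beat = cands$start_beat[i], end_beat = cands$end_beat[i],
           rc_run_length = cands$rc_run_length[i], verdict = v$klass,
           geminy_pattern = isTRUE(v$evidence$geminy_pattern))
  })
  verdicts <- if (length(verdicts)) list_rbind(verdicts) else
    tibble(start_beat = integer(), end_beat = integer(),
           rc_run_length = integer(), verdict = character(),
           geminy_pattern = logical())

  # An Rc value at beat i describes the six intervals i..i+5, so a flagged
  # run [s, e) is evidence for irregular rhythm anywhere inside beats
  # s..e+5. Boundary windows flag with only part of their span inside the
  # episode, so claiming the full span at one end biases the offset late;
  # splitting the window span symmetrically (+3 beats at each edge) centres
  # the detected segment on the episode.
  af <- verdicts[verdicts$verdict == "AF", , drop = FALSE]
  detections <- tibble(
    start_beat = pmin.int(af$start_beat + 3L, n_beats),
    end_beat = pmin.int(af$end_beat + 3L, n_beats + 1L))

  structure(
    list(detections = detections, verdicts = verdicts, rc = rc,
         n_beats = n_beats, beats = beats, config = config),
    class = "paf_detection")
}

resolve_input <- function(input, config) {
  if (inherits(input, "paf_recording")) return(input$beats)
  if (inherits(input, "wfdb_record")) {
    input <- list(signal = input$signal[, 1], fs = input$fs)
  }
  if (inherits(input, "paf_ecg")) {
    input <- list(signal = input$signal, fs = input$fs)
  }
  if (is.list(input) && !is.data.frame(input) &&
      all(c("signal", "fs") %in% names(input))) {
    return(preprocess_waveform(input$signal, input$fs, config))
  }
  if (is.numeric(input)) {
    return(tibble(beat = seq_len(length(input) + 1L),
                  rr_s = c(as.numeric(input), NA_real_)))
  }
  if (is.data.frame(input)) {
    if (!"rr_s" %in% names(input))
      abort("RR-mode input needs an `rr_s` column.")
    if (!"beat" %in% names(input))
      input <- mutate(input, beat = dplyr::row_number())
    return(input)
  }
  abort("unsupported input type for `detect_paf()`.")
}

# Waveform-mode front end: filter, gate, detect, refine, derive RRs.
preprocess_waveform <- function(signal, fs, config) {
  clean <- remove_baseline(signal, fs, config$baseline_win1_ms,
                           config$baseline_win2_ms)
  mask <- assess_quality(clean, fs, window_s = config$sqa_window_s,
                         flat_mv = config$sqa_flat_mv,
                         sat_frac = config$sqa_sat_frac,
                         peak_mad_factor = config$sqa_peak_mad_factor)
  beats <- detect_qrs(clean, fs)
  beats <- refine_qrs(clean, beats, fs,
                      radius_ms = config$qrs_refine_radius_ms)
  beats <- unique(beats)
  rr_from_beats(beats, fs, quality = mask)
}

#' @export
print.paf_detection <- function(x, ...) {
  cat(sprintf("<paf_detection> %d beats: %d candidate(s), %d AF segment(s)\n",
              x$n_beats, nrow(x$verdicts), nrow(x$detections)))
  if (nrow(x$detections)) {
    d <- x$detections
    cat(sprintf("  [%d, %d)\n", d$start_beat, d$end_beat), sep = "")
  }
  invisible(x)
}

#' @describeIn detect_paf Detected PAF segments as a tibble.
#' @param x A `paf_detection`.
#' @param ... Unused.
#' @method tidy paf_detection
#' @export
tidy.paf_detection <- function(x, ...) x$detections

#' @describeIn detect_paf One-row run summary (candidates, verdict counts,
#'   AF beat burden).
#' @method glance paf_detection
#' @export
glance.paf_detection <- function(x, ...) {
  v <- x$verdicts$verdict
  af_beats <- sum(x$detections$end_beat - x$detections$start_beat)
  tibble(n_beats = x$n_beats,
         n_candidates = nrow(x$verdicts),
         n_af = sum(v == "AF"),
         n_single_pb = sum(v == "SINGLE_PB"),
         n_multi_pb = sum(v == "MULTI_PB"),
         n_geminy = sum(v == "GEMINY"),
         af_beat_fraction = af_beats / x$n_beats,
         threshold = x$config$threshold)
}

#' Evaluate a detection run against its recording's ground truth
#'
#' Convenience wrapper: takes the detection result of a synthetic
#' `paf_recording` (or explicit label segments) and produces the full
#' [evaluate_detection()] report against the AFIB ground-truth segments.
#'
#' @param det A `paf_detection`.
#' @param truth A `paf_recording`, or a data frame of labelled AF segments
#'   (`start`/`end`).
#' @inheritParams segment_score
#' @return A `paf_eval`.
#' @export
evaluate_against <- function(det, truth, tol_beats = 3L) {
  stopifnot(inherits(det, "paf_detection"))
  labels <- if (inherits(truth, "paf_recording")) {
    segs <- recording_segments(truth)
    segs[segs$label == "AFIB", c("start", "end")]
  } else truth
  evaluate_detection(labels, det$detections, total_beats = det$n_beats,
                     tol_beats = tol_beats)
}
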