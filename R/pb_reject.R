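#' Premature-beat rejection cascade
#'
#' A candidate (suspected-AF) segment flagged by the rhythm-change screen can
#' be caused either by genuine AF or by premature-beat rhythms. The cascade
#' applies three rejection tests in order:
#'
#' 1. **Single premature beat**: one ectopic beat perturbs exactly 7 of the
#'    sliding 6-RR windows, so candidates whose longest continuous flagged
#'    run does not exceed `single_pb_max_run` beats (default 10) are rejected
#'    outright.
#' 2. **Bigeminy / trigeminy**: after K-medoids clustering of the segment's
#'    RR features, a geminal pattern is declared when some 6-consecutive-RR
#'    window holds equally many longest-group and shortest-group intervals,
#'    both at least `geminy_min_count`. The longest-interval group is then
#'    re-screened: if all its Rc values sit at or below the threshold the
#'    candidate is a geminal rhythm, not AF.
#' 3. **Frequent (multi) premature beats**: the group whose mean RR lies
#'    closest to the segment median -- the normal beats, which remain the
#'    majority -- is re-screened the same way; a quiet recheck rejects the
#'    candidate as frequent ectopy.
#'
#' A candidate is classified AF only when every test fails to fire.
#'
#' @name pb_reject
NULL

#' Single-premature-beat run-length rule
#'
#' @param rc_run_length Longest continuous flagged run of a candidate, in
#'   beats (from [candidate_segments()]).
#' @param max_run Longest run still attributable to isolated ectopy
#'   (default 10 beats; a lone premature beat perturbs 7 windows).
#' @return `TRUE` when the candidate is rejected as a single premature beat,
#'   i.e. its run length does not exceed `max_run`.
#' @export
single_pb_recheck <- function(rc_run_length, max_run = 10L) {
  assert_count(max_run, "max_run", min = 1L)
  rc_run_length <= max_run
}

#' Group closest to the segment's median RR
#'
#' Picks the cluster whose mean RR lies closest to the median of all the
#' segment's intervals -- with frequent ectopy the normal beats still form
#' the majority, so this recovers the underlying sinus intervals. Ties go to
#' the larger group, then the lower group id.
#'
#' @param clusters A `paf_cluster` from [cluster_rr()].
#' @return A group id (integer).
#' @export
select_median_group <- function(clusters) {
  stopifnot(inherits(clusters, "paf_cluster"))
  ids <- sort(unique(clusters$assignment))
  if (length(ids) == 1L) return(ids)
  med <- median(clusters$rr)
  dev <- abs(clusters$group_means - med)
  sizes <- clusters$group_sizes
  ord <- order(dev, -sizes, ids)
  ids[ord[1]]
}

#' Re-screen a selected RR subsequence
#'
#' Recomputes the rhythm-change statistic over the selected intervals
#' (concatenated in their original temporal order) with 6-RR windows and
#' reports whether every defined value stays at or below the threshold.
#' Selections too short to form a window (< 6 intervals) carry no evidence
#' either way; by default they do **not** reject the candidate (`short =
#' "keep"`), because every premature-beat rhythm the cascade targets leaves a
#' large selected group (the normal beats of frequent ectopy, the pauses of a
#' geminal run), whereas tiny groups arise from chance splits of AF
#' intervals. Set `short = "reject"` to treat short selections as quiet.
#'
#' @param rr_selected Numeric vector of selected RR intervals, temporal order.
#' @param threshold Screening threshold on Rc.
#' @param short Verdict for selections shorter than one window: `"keep"`
#'   (return `FALSE`, default) or `"reject"` (return `TRUE`).
#' @inheritParams compute_rc
#' @return `TRUE` iff all defined Rc values are `<= threshold`.
#' @export
recheck_rc <- function(rr_selected, threshold = 0.05,
                       std_mode = c("population", "sample"),
                       short = c("keep", "reject")) {
  std_mode <- match.arg(std_mode)
  short <- match.arg(short)
  assert_positive_scalar(threshold, "threshold")
  n <- length(rr_selected)
  if (n < 6L) return(short == "reject")
  s <- rc_series(as.numeric(rr_selected), threshold = threshold,
                 std_mode = std_mode)
  vals <- s$rc[!is.na(s$rc)]
  all(vals <= threshold)
}

#' Geminal (bigeminy/trigeminy) RR pattern test
#'
#' Bigeminy alternates short/long intervals, trigeminy cycles
#' short/long/normal; in both, any 6 consecutive intervals hold equally many
#' longest-group and shortest-group members (3+3 for bigeminy, 2+2 for
#' trigeminy). The test scans every 6-interval window of the segment for such
#' a balanced occupancy with both counts at least `min_count`.
#'
#' @inheritParams select_median_group
#' @param min_count Minimum occurrences of each extreme group inside the
#'   window. The default 3 is the strict reading of the rule (a bigeminy
#'   window holds 3+3); with `min_count = 2` a trigeminy window (2+2)
#'   satisfies the rule directly, but chance arrangements of AF intervals
#'   then qualify far more often. Under the strict default trigeminy is
#'   still eliminated, through the frequent-ectopy recheck.
#' @return `TRUE` when some window shows the balanced pattern.
#' @export
geminy_pattern_present <- function(clusters, min_count = 3L) {
  stopifnot(inherits(clusters, "paf_cluster"))
  assert_count(min_count, "min_count", min = 1L)
  g <- clusters$assignment
  if (length(g) < 6L) return(FALSE)
  lo <- min(g); hi <- max(g)
  if (lo == hi) return(FALSE)
  is_lo <- as.integer(g == lo)
  is_hi <- as.integer(g == hi)
  cs_lo <- c(0L, cumsum(is_lo))
  cs_hi <- c(0L, cumsum(is_hi))
  i <- seq_len(length(g) - 5L)
  n_lo <- cs_lo[i + 6L] - cs_lo[i]
  n_hi <- cs_hi[i + 6L] - cs_hi[i]
  any(n_lo == n_hi & n_lo >= min_count)
}

#' Geminal rhythm recheck
#'
#' Given a present geminal pattern, re-screens the longest-interval group:
#' the compensatory pauses of bigeminy/trigeminy are nearly uniform, so their
#' Rc values drop below threshold, while AF intervals that merely mimic the
#' pattern stay variable.
#'
#' @inheritParams select_median_group
#' @inheritParams recheck_rc
#' @return `TRUE` when the candidate is rejected as bigeminy/trigeminy.
#' @export
geminy_recheck <- function(clusters, threshold = 0.05,
                           std_mode = c("population", "sample")) {
  stopifnot(inherits(clusters, "paf_cluster"))
  std_mode <- match.arg(std_mode)
  hi <- max(clusters$assignment)
  recheck_rc(clusters$rr[clusters$assignment == hi], threshold, std_mode)
}

#' Classify one candidate segment
#'
#' Runs the full rejection cascade on a candidate from
#' [candidate_segments()]: single-PB run-length rule, then K-medoids
#' clustering of the intervals spanned by the candidate's flagged windows,
#' then the geminal and multi-PB rechecks. The candidate is AF only when no
#' test fires.
#'
#' @param candidate One-row data frame (or list) with `start_beat`,
#'   `end_beat`, `rc_run_length`.
#' @param rr Full per-beat RR vector of the recording (`rr[i]` is the
#'   interval after beat `i`).
#' @param threshold Screening threshold on Rc.
#' @param single_pb_max_run Run-length bound of the single-PB rule.
#' @param geminy_min_count Minimum per-window extreme-group count of the
#'   geminal pattern test.
#' @inheritParams compute_rc
#' @param seed Optional seed forwarded to [cluster_rr()].
#' @return A `paf_verdict`: list with `klass` (one of `"AF"`, `"SINGLE_PB"`,
#'   `"MULTI_PB"`, `"GEMINY"`), and `evidence` (run length, pattern flag,
#'   recheck outcomes, cluster summary).
#' @export
classify_candidate <- function(candidate, rr, threshold = 0.05,
                               single_pb_max_run = 10L,
                               geminy_min_count = 3L,
                               std_mode = c("population", "sample"),
                               seed = NULL) {
  std_mode <- match.arg(std_mode)
  start <- candidate$start_beat[1]
  end <- candidate$end_beat[1]
  run_len <- candidate$rc_run_length[1]

  if (single_pb_recheck(run_len, single_pb_max_run)) {
    return(new_verdict("SINGLE_PB", run_len, pattern = NA, geminy_ok = NA,
                       multi_ok = NA, clusters = NULL))
  }

  # Intervals covered by the candidate's flagged windows: window at beat i
  # spans intervals i .. i+5.
  n_rr <- length(rr)
  idx <- start:min(end - 1L + 5L, n_rr)
  rr_seg <- rr[idx]
  rr_seg <- rr_seg[!is.na(rr_seg)]
  if (length(rr_seg) < 6L) {
    return(new_verdict("SINGLE_PB", run_len, pattern = NA, geminy_ok = NA,
                       multi_ok = NA, clusters = NULL))
  }

  cl <- cluster_rr(rr_seg, seed = seed)

  pattern <- geminy_pattern_present(cl, geminy_min_count)
  if (pattern) {
    gem <- geminy_recheck(cl, threshold, std_mode)
    if (gem) {
      return(new_verdict("GEMINY", run_len, pattern = TRUE, geminy_ok = TRUE,
                         multi_ok = NA, clusters = cl))
    }
  } else {
    gem <- NA
  }

  sel <- select_median_group(cl)
  multi <- recheck_rc(cl$rr[cl$assignment == sel], threshold, std_mode)
  if (multi) {
    return(new_verdict("MULTI_PB", run_len, pattern = pattern,
                       geminy_ok = if (pattern) FALSE else NA,
                       multi_ok = TRUE, clusters = cl))
  }
  new_verdict("AF", run_len, pattern = pattern,
              geminy_ok = if (pattern) FALSE else NA,
              multi_ok = FALSE, clusters = cl)
}

new_verdict <- function(klass, run_len, pattern, geminy_ok, multi_ok,
                        clusters) {
  structure(
    list(klass = klass,
         evidence = list(rc_run_length = run_len,
                         geminy_pattern = pattern,
                         geminy_rejected = geminy_ok,
                         multi_rejected = multi_ok),
         clusters = clusters),
    class = "paf_verdict")
}

#' @export
print.paf_verdict <- function(x, ...) {
  cat(sprintf("<paf_verdict> %s (run length %d)\n", x$klass,
              x$evidence$rc_run_length))
  invisible(x)
}
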