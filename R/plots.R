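# ggplot2 views of the main result types.

#' @describeIn rc_series Plot RR intervals and the Rc series with the
#'   screening threshold; flagged beats are highlighted.
#' @param object A `tbl_rc`.
#' @param ... Unused.
#' @method autoplot tbl_rc
#' @export
autoplot.tbl_rc <- function(object, ...) {
  thr <- attr(object, "threshold")
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beat)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$rc), na.rm = TRUE,
                       colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$rc, colour = .data$flagged),
                        na.rm = TRUE, size = 1) +
    ggplot2::geom_hline(yintercept = thr, linetype = 2, colour = "blue") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "red"),
                                 name = "flagged") +
    ggplot2::labs(x = "beat", y = "Rc (sd/mean of next 6 RRs)",
                  title = sprintf("Rhythm-change screen (threshold %.3g)",
                                  thr)) +
    ggplot2::theme_minimal()
}

#' @describeIn detect_paf Plot the RR series with detected PAF segments
#'   shaded.
#' @param object A `paf_detection`.
#' @method autoplot paf_detection
#' @export
autoplot.paf_detection <- function(object, ...) {
  beats <- as_tibble(object$beats)
  p <- ggplot2::ggplot(beats, ggplot2::aes(x = .data$beat, y = .data$rr_s)) +
    ggplot2::geom_line(na.rm = TRUE, colour = "grey40") +
    ggplot2::labs(x = "beat", y = "RR (s)", title = "Detected PAF segments") +
    ggplot2::theme_minimal()
  if (nrow(object$detections)) {
    p <- p + ggplot2::geom_rect(
      data = object$detections,
      ggplot2::aes(xmin = .data$start_beat, xmax = .data$end_beat,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "red", alpha = 0.15)
  }
  p
}

#' @describeIn evaluate_detection Plot labelled vs detected segments and the
#'   per-segment PAF-scores.
#' @param object A `paf_eval`.
#' @method autoplot paf_eval
#' @export
autoplot.paf_eval <- function(object, ...) {
  L <- mutate(object$labels, what = "labelled", y = 1)
  D <- mutate(object$detections, what = "detected", y = 0)
  segs <- dplyr::bind_rows(L, D)
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end, y = .data$y,
                   yend = .data$y, colour = .data$what),
      linewidth = 4) +
    ggplot2::geom_text(
      data = mutate(object$per_segment, mid = (.data$start + .data$end) / 2),
      ggplot2::aes(x = .data$mid, y = 1.25,
                   label = sprintf("%.2f", .data$score)), size = 3) +
    ggplot2::scale_y_continuous(breaks = c(0, 1),
                                labels = c("detected", "labelled"),
                                limits = c(-0.5, 1.5)) +
    ggplot2::labs(x = "beat", y = NULL,
                  title = sprintf("PAF-score %.3f (error %d, missed %d)",
                                  object$average_score,
                                  object$error_segments,
                                  object$missed_segments),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
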