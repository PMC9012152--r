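#' Specify a synthetic rhythm segment
#'
#' A `rhythm_spec` describes one homogeneous rhythm episode for the synthetic
#' generator: normal sinus rhythm (NSR), atrial fibrillation (AF), or one of
#' four premature-beat (PB) patterns. The generator draws NSR as a mildly
#' autocorrelated sequence around `base_rr`, AF as independent highly variable
#' intervals, and premature beats as a short coupling interval followed by a
#' compensatory pause, both proportional to the local mean RR.
#'
#' @param rhythm_class One of `"NSR"`, `"AF"`, `"SINGLE_PB"`, `"MULTI_PB"`,
#'   `"BIGEMINY"`, `"TRIGEMINY"`.
#' @param n_beats Number of beats (>= 7 so at least one 6-RR screening window
#'   exists).
#' @param base_rr Mean RR interval in seconds (default 0.8 s, i.e. 75 bpm).
#' @param nsr_cv Coefficient of variation of the NSR backbone (default 0.03).
#' @param af_cv Coefficient of variation of AF intervals (default 0.20).
#' @param coupling_fraction Premature RR as a fraction of the local mean RR,
#'   in (0, 1) (default 0.6).
#' @param compensatory_fraction Post-ectopic pause as a multiple of the local
#'   mean RR, > 1 (default 1.4).
#' @param n_pb Number of premature beats for `MULTI_PB` (default 4).
#' @param seed Optional integer seed making the draw reproducible.
#'
#' @return A `rhythm_spec` object (validated list).
#' @seealso [gen_rr()], [gen_recording()]
#' @export
rhythm_spec <- function(rhythm_class = c("NSR", "AF", "SINGLE_PB", "MULTI_PB",
                                         "BIGEMINY", "TRIGEMINY"),
                        n_beats = 31L, base_rr = 0.8, nsr_cv = 0.03,
                        af_cv = 0.20, coupling_fraction = 0.6,
                        compensatory_fraction = 1.4, n_pb = 4L, seed = NULL) {
  rhythm_class <- match.arg(toupper(rhythm_class[1]),
                            c("NSR", "AF", "SINGLE_PB", "MULTI_PB",
                              "BIGEMINY", "TRIGEMINY"))
  n_beats <- assert_count(n_beats, "n_beats", min = 1L)
  assert_positive_scalar(base_rr, "base_rr")
  if (!is.numeric(nsr_cv) || nsr_cv < 0 || nsr_cv >= 1)
    abort("`nsr_cv` must be in [0, 1).")
  if (!is.numeric(af_cv) || af_cv < 0 || af_cv >= 1)
    abort("`af_cv` must be in [0, 1).")
  if (!is.numeric(coupling_fraction) || coupling_fraction <= 0 ||
      coupling_fraction >= 1)
    abort("`coupling_fraction` must lie strictly between 0 and 1.")
  if (!is.numeric(compensatory_fraction) || compensatory_fraction <= 1)
    abort("`compensatory_fraction` must be > 1.")
  n_pb <- assert_count(n_pb, "n_pb", min = 1L)
  structure(
    list(rhythm_class = rhythm_class, n_beats = n_beats, base_rr = base_rr,
         nsr_cv = nsr_cv, af_cv = af_cv, coupling_fraction = coupling_fraction,
         compensatory_fraction = compensatory_fraction, n_pb = n_pb,
         seed = seed),
    class = "rhythm_spec")
}

#' @export
print.rhythm_spec <- function(x, ...) {
  cat(sprintf("<rhythm_spec> %s, %d beats, base RR %.3g s\n",
              x$rhythm_class, x$n_beats, x$base_rr))
  invisible(x)
}

# Physiological truncation bounds for generated RR intervals (seconds).
RR_BOUNDS <- c(0.2, 2.5)

clamp_rr <- function(rr) pmin(pmax(rr, RR_BOUNDS[1]), RR_BOUNDS[2])

# AR(1) backbone around base_rr with marginal sd = cv * base_rr.
nsr_backbone <- function(n, base_rr, cv, phi = 0.5) {
  sigma <- cv * base_rr
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sigma)
  if (n > 1) {
    eps <- rnorm(n - 1, 0, sigma * sqrt(1 - phi^2))
    for (i in 2:n) x[i] <- phi * x[i - 1] + eps[i - 1]
  }
  base_rr + x
}

# Mean of up to 6 preceding backbone RRs (rate-adaptive PB scaling).
local_mean <- function(rr, i) {
  lo <- max(1L, i - 6L)
  if (lo > i) return(rr[i])
  mean(rr[lo:i])
}

# Sample n_pb PB beat positions in [4, n-3] with pairwise spacing >= 3.
sample_pb_positions <- function(n_beats, n_pb) {
  lo <- 4L; hi <- n_beats - 3L
  if (hi < lo || (hi - lo) %/% 3L + 1L < n_pb) {
    abort(sprintf(
      "`n_beats` (%d) too small to place %d premature beats with spacing 3.",
      n_beats, n_pb))
  }
  for (attempt in 1:200) {
    pos <- sort(sample(lo:hi, n_pb))
    if (n_pb == 1L || all(diff(pos) >= 3L)) return(pos)
  }
  # Deterministic fallback: evenly spread.
  as.integer(round(seq(lo, hi, length.out = n_pb)))
}

#' Generate an annotated RR-interval sequence
#'
#' Draws one rhythm episode according to a [rhythm_spec()]. The result is a
#' per-beat tibble: `n_beats` beats carry `n_beats - 1` RR intervals (`rr_s` is
#' the interval *after* each beat; `NA` on the last beat). A beat is labelled
#' `"PB"` when it terminates a coupling (short) interval; all other beats are
#' `"N"`. All intervals are truncated to the physiological range 0.2--2.5 s.
#'
#' Pattern construction:
#' * `SINGLE_PB` places exactly one PB, at least 3 beats from either end, as a
#'   coupling interval (`coupling_fraction` x local mean RR) followed by a
#'   compensatory pause (`compensatory_fraction` x local mean RR).
#' * `MULTI_PB` places `n_pb` such beats with pairwise spacing >= 3 beats.
#' * `BIGEMINY` alternates short/long intervals throughout; `TRIGEMINY`
#'   repeats short/long/normal.
#'
#' @param spec A [rhythm_spec()].
#' @return A tibble with columns `beat`, `time_s`, `rr_s`, `beat_label`.
#' @examples
#' gen_rr(rhythm_spec("BIGEMINY", n_beats = 11, seed = 1))
#' @export
gen_rr <- function(spec) {
  if (!inherits(spec, "rhythm_spec")) abort("`spec` must be a rhythm_spec.")
  if (spec$n_beats < 7L) abort("`n_beats` must be >= 7.")
  with_seed(spec$seed, gen_rr_impl(spec))
}

gen_rr_impl <- function(spec) {
  n <- spec$n_beats
  n_rr <- n - 1L
  cf <- spec$coupling_fraction
  pf <- spec$compensatory_fraction
  backbone <- nsr_backbone(n_rr, spec$base_rr, spec$nsr_cv)
  label <- rep("N", n)

  rr <- switch(
    spec$rhythm_class,
    NSR = backbone,
    AF = rnorm(n_rr, spec$base_rr, spec$af_cv * spec$base_rr),
    SINGLE_PB = {
      p <- sample_pb_positions(n, 1L)
      lm <- local_mean(backbone, p - 2L)
      out <- backbone
      out[p - 1L] <- cf * lm
      out[p] <- pf * lm
      label[p] <- "PB"
      out
    },
    MULTI_PB = {
      pos <- sample_pb_positions(n, spec$n_pb)
      out <- backbone
      for (p in pos) {
        lm <- local_mean(backbone, p - 2L)
        out[p - 1L] <- cf * lm
        out[p] <- pf * lm
      }
      label[pos] <- "PB"
      out
    },
    BIGEMINY = {
      idx <- seq_len(n_rr)
      out <- ifelse(idx %% 2L == 1L, cf * backbone, pf * backbone)
      pb <- seq(2L, n, by = 2L)
      label[pb] <- "PB"
      out
    },
    TRIGEMINY = {
      idx <- seq_len(n_rr)
      out <- backbone
      out[idx %% 3L == 1L] <- cf * backbone[idx %% 3L == 1L]
      out[idx %% 3L == 2L] <- pf * backbone[idx %% 3L == 2L]
      pb <- seq(2L, n, by = 3L)
      label[pb] <- "PB"
      out
    })

  rr <- clamp_rr(rr)
  tibble(
    beat = seq_len(n),
    time_s = c(0, cumsum(rr)),
    rr_s = c(rr, NA_real_),
    beat_label = label)
}

#' Concatenate rhythm episodes into an annotated synthetic recording
#'
#' Emulates a long-term ECG recording in which AF and non-AF segments follow
#' each other: episodes are concatenated beat-wise in order and each episode
#' boundary is marked on its first beat. The joining interval between two
#' episodes is the next episode's `base_rr`, so the ground truth stays exactly
#' recoverable.
#'
#' @param episodes A list of episodes, each `list(spec = <rhythm_spec>,
#'   label = "AFIB" or "N")`.
#' @param seed Optional integer seed; episodes without their own seed draw
#'   from this stream.
#' @return A `paf_recording`: list with `beats` (tibble `beat`, `time_s`,
#'   `rr_s`, `beat_label`, `rhythm_label`) and `annotation` (tibble
#'   `start_beat`, `rhythm_label`).
#' @examples
#' rec <- gen_recording(list(
#'   list(spec = rhythm_spec("NSR", 50), label = "N"),
#'   list(spec = rhythm_spec("AF", 40), label = "AFIB")), seed = 1)
#' recording_segments(rec)
#' @export
gen_recording <- function(episodes, seed = NULL) {
  if (!is.list(episodes) || length(episodes) == 0L)
    abort("`episodes` must be a non-empty list.")
  ok <- map_lgl(episodes, function(e)
    is.list(e) && inherits(e$spec, "rhythm_spec") && is.character(e$label))
  if (!all(ok))
    abort("each episode must be list(spec = <rhythm_spec>, label = <chr>).")

  with_seed(seed, {
    parts <- map(episodes, function(e) gen_rr(e$spec))
    labels <- map_chr(episodes, "label")
    n_ep <- length(parts)
    start_beat <- integer(n_ep)
    offset <- 0L
    rr_all <- numeric(0)
    beat_label <- character(0)
    rhythm_label <- character(0)
    for (k in seq_len(n_ep)) {
      nk <- nrow(parts[[k]])
      start_beat[k] <- offset + 1L
      rr_k <- parts[[k]]$rr_s[-nk]
      # joining interval into the next episode's first beat
      if (k < n_ep) rr_k <- c(rr_k, episodes[[k + 1L]]$spec$base_rr)
      rr_all <- c(rr_all, rr_k)
      beat_label <- c(beat_label, parts[[k]]$beat_label)
      rhythm_label <- c(rhythm_label, rep(labels[k], nk))
      offset <- offset + nk
    }
    beats <- tibble(
      beat = seq_len(offset),
      time_s = c(0, cumsum(rr_all)),
      rr_s = c(rr_all, NA_real_),
      beat_label = beat_label,
      rhythm_label = rhythm_label)
    structure(
      list(beats = beats,
           annotation = tibble(start_beat = start_beat,
                               rhythm_label = labels),
           seed = seed),
      class = "paf_recording")
  })
}

#' @importFrom purrr map_chr
#' @export
print.paf_recording <- function(x, ...) {
  cat(sprintf("<paf_recording> %d beats, %d episode(s), %d AFIB episode(s)\n",
              nrow(x$beats), nrow(x$annotation),
              sum(x$annotation$rhythm_label == "AFIB")))
  invisible(x)
}

#' Ground-truth rhythm segments of a synthetic recording
#'
#' Collapses the per-beat rhythm labels of a recording into maximal half-open
#' `[start, end)` beat-index segments of constant label.
#'
#' @param rec A `paf_recording` from [gen_recording()].
#' @return A tibble with columns `start`, `end`, `label`.
#' @export
recording_segments <- function(rec) {
  stopifnot(inherits(rec, "paf_recording"))
  r <- rle(rec$beats$rhythm_label)
  ends <- cumsum(r$lengths)
  tibble(start = ends - r$lengths + 1L, end = ends + 1L, label = r$values)
}

#' Render a synthetic single-lead ECG waveform from a recording
#'
#' Places one QRS-like template (a Gaussian-windowed biphasic pulse, width
#' about 80 ms, absolute maximum at its centre) per beat at the cumulative RR
#' times, then adds a low-frequency sinusoidal baseline wander and white
#' noise. The exact sample index of each template centre is returned as ground
#' truth for QRS-detector testing.
#'
#' @param rec A `paf_recording` or a per-beat tibble from [gen_rr()].
#' @param fs Sampling frequency in Hz (>= 100 so the template is resolvable).
#' @param qrs_amplitude QRS peak amplitude in mV.
#' @param baseline_wander_amp Amplitude (mV) of a 0.3 Hz sinusoidal drift.
#' @param noise_sd Standard deviation (mV) of additive white noise.
#' @param pad_s Flat padding added before the first and after the last beat.
#' @param seed Optional integer seed for the noise draw.
#' @return A `paf_ecg`: list with `signal` (mV), `fs`, `true_qrs` (sample
#'   indices of template centres) and `beats` (the input beat table).
#' @export
render_ecg <- function(rec, fs = 250, qrs_amplitude = 1,
                       baseline_wander_amp = 0, noise_sd = 0,
                       pad_s = 0.25, seed = NULL) {
  beats <- if (inherits(rec, "paf_recording")) rec$beats else rec
  if (!is.data.frame(beats) || !all(c("time_s") %in% names(beats)))
    abort("`rec` must be a paf_recording or a gen_rr() beat table.")
  if (fs < 100) abort("`fs` must be >= 100 Hz to represent the QRS template.")

  with_seed(seed, {
    t_beat <- beats$time_s + pad_s
    n <- as.integer(round((max(t_beat) + pad_s) * fs)) + 1L
    centre <- as.integer(round(t_beat * fs)) + 1L

    half_w <- as.integer(round(0.04 * fs))
    tt <- (-half_w:half_w) / fs
    template <- qrs_amplitude * exp(-tt^2 / (2 * 0.012^2)) *
      cos(2 * pi * 12.5 * tt)

    sig <- numeric(n)
    for (c0 in centre) {
      idx <- (c0 - half_w):(c0 + half_w)
      keep <- idx >= 1L & idx <= n
      sig[idx[keep]] <- sig[idx[keep]] + template[keep]
    }
    tsamp <- (seq_len(n) - 1L) / fs
    if (baseline_wander_amp > 0)
      sig <- sig + baseline_wander_amp * sin(2 * pi * 0.3 * tsamp)
    if (noise_sd > 0)
      sig <- sig + rnorm(n, 0, noise_sd)

    structure(list(signal = sig, fs = fs, true_qrs = centre, beats = beats),
              class = "paf_ecg")
  })
}

#' @export
print.paf_ecg <- function(x, ...) {
  cat(sprintf("<paf_ecg> %d samples at %g Hz, %d beats\n",
              length(x$signal), x$fs, length(x$true_qrs)))
  invisible(x)
}

#' Write / read a recording as delimited text
#'
#' One row per beat with columns `beat_index`, `time_s`, `rr_s`, `beat_label`,
#' `rhythm_label`. `read_rr_csv()` restores a `paf_recording`.
#'
#' @param rec A `paf_recording` (or `gen_rr()` tibble, written with rhythm
#'   label `"N"`).
#' @param path File path.
#' @return `write_rr_csv()` returns `path` invisibly; `read_rr_csv()` a
#'   `paf_recording`.
#' @export
write_rr_csv <- function(rec, path) {
  beats <- if (inherits(rec, "paf_recording")) rec$beats else
    mutate(rec, rhythm_label = "N")
  out <- data.frame(beat_index = beats$beat, time_s = beats$time_s,
                    rr_s = beats$rr_s, beat_label = beats$beat_label,
                    rhythm_label = beats$rhythm_label)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rr_csv
#' @export
read_rr_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("beat_index", "rr_s")
  if (!all(need %in% names(d)))
    abort(sprintf("%s: missing required columns %s", path,
                  paste(setdiff(need, names(d)), collapse = ", ")))
  n <- nrow(d)
  rr <- d$rr_s
  time_s <- if ("time_s" %in% names(d)) d$time_s else c(0, cumsum(rr[-n]))
  beat_label <- if ("beat_label" %in% names(d)) d$beat_label else rep("N", n)
  rhythm_label <- if ("rhythm_label" %in% names(d)) d$rhythm_label
                  else rep("N", n)
  beats <- tibble(beat = seq_len(n), time_s = time_s, rr_s = rr,
                  beat_label = beat_label, rhythm_label = rhythm_label)
  r <- rle(rhythm_label)
  ends <- cumsum(r$lengths)
  structure(
    list(beats = beats,
         annotation = tibble(start_beat = ends - r$lengths + 1L,
                             rhythm_label = r$values),
         seed = NULL),
    class = "paf_recording")
}
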