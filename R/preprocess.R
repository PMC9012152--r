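#' Remove baseline wander with a two-pass sliding median filter
#'
#' Estimates the baseline by two successive running medians (a short window
#' that straddles QRS complexes, then a longer one that smooths the
#' estimate) and subtracts it. Both passes are zero-phase (centred windows),
#' so QRS timing is untouched and the sample count is preserved.
#'
#' @param signal Numeric vector, one ECG lead in mV.
#' @param fs Sampling frequency in Hz (>= 100).
#' @param win1_ms,win2_ms Window lengths of the two median passes
#'   (defaults 200 and 600 ms).
#' @return Numeric vector of the same length, baseline removed.
#' @export
remove_baseline <- function(signal, fs, win1_ms = 200, win2_ms = 600) {
  if (fs < 100) abort("`fs` must be >= 100 Hz.")
  k1 <- odd_window(win1_ms / 1000 * fs)
  k2 <- odd_window(win2_ms / 1000 * fs)
  if (length(signal) <= max(k1, k2))
    abort("signal shorter than the median-filter window.")
  base <- stats::runmed(stats::runmed(signal, k1, endrule = "median"),
                        k2, endrule = "median")
  as.numeric(signal - base)
}

odd_window <- function(k) {
  k <- max(3L, as.integer(round(k)))
  if (k %% 2L == 0L) k + 1L else k
}

#' Signal-quality mask over fixed windows
#'
#' Splits the (baseline-removed) signal into consecutive windows and flags a
#' window unusable when it carries no usable ECG information: flatline
#' (peak-to-peak below `flat_mv`), saturation (more than `sat_frac` of the
#' samples pinned at the record's min/max rail), or no QRS-like peak (maximum
#' absolute amplitude below `peak_mad_factor` times the window's scaled
#' median absolute deviation, the signature of formless noise). Beats whose
#' sample falls in an unusable window are dropped downstream.
#'
#' @param signal Numeric vector (mV), baseline removed.
#' @param fs Sampling frequency (Hz).
#' @param window_s Window length in seconds (default 2).
#' @param flat_mv Peak-to-peak flatline bound in mV (default 0.05, i.e.
#'   50 microvolt).
#' @param sat_frac Maximum tolerated fraction of rail-pinned samples
#'   (default 0.2).
#' @param peak_mad_factor Required ratio of peak amplitude to scaled MAD
#'   (default 4).
#' @return A `quality_mask`: tibble with `window`, `start_sample`,
#'   `end_sample` (half-open), `usable`; attributes `fs`, `window_s`.
#' @export
assess_quality <- function(signal, fs, window_s = 2, flat_mv = 0.05,
                           sat_frac = 0.2, peak_mad_factor = 4) {
  n <- length(signal)
  win <- max(1L, as.integer(round(window_s * fs)))
  n_win <- ceiling(n / win)
  if (n == 0L) {
    out <- tibble(window = integer(), start_sample = integer(),
                  end_sample = integer(), usable = logical())
  } else {
    rail_lo <- min(signal); rail_hi <- max(signal)
    usable <- logical(n_win)
    start <- integer(n_win); end <- integer(n_win)
    for (w in seq_len(n_win)) {
      s <- (w - 1L) * win + 1L
      e <- min(n, w * win)
      start[w] <- s; end[w] <- e + 1L
      x <- signal[s:e]
      p2p <- max(x) - min(x)
      flat <- p2p < flat_mv
      sat <- mean(x == rail_lo | x == rail_hi) > sat_frac && p2p > 0
      no_qrs <- max(abs(x)) < peak_mad_factor * stats::mad(x)
      usable[w] <- !(flat || sat || no_qrs)
    }
    out <- tibble(window = seq_len(n_win), start_sample = start,
                  end_sample = end, usable = usable)
  }
  attr(out, "fs") <- fs
  attr(out, "window_s") <- window_s
  class(out) <- c("quality_mask", class(out))
  out
}

# Which mask window does each sample fall in; TRUE when usable (or no mask).
sample_usable <- function(samples, mask) {
  if (is.null(mask) || nrow(mask) == 0L) return(rep(TRUE, length(samples)))
  win <- attr(mask, "window_s") * attr(mask, "fs")
  w <- pmin(nrow(mask), (samples - 1L) %/% as.integer(round(win)) + 1L)
  mask$usable[w]
}

#' Detect QRS complexes
#'
#' A derivative-energy detector: band-pass 5--15 Hz (3rd-order Butterworth,
#' forward-backward so zero phase), squared derivative, centred 100 ms moving
#' average (matching the QRS duration, so the envelope peaks sharply on the
#' complex), then adaptive peak picking with separate signal/noise running
#' levels and a 200 ms refractory period. Detections should be passed through
#' [refine_qrs()] to land exactly on the waveform extremum.
#'
#' @param signal Numeric vector (mV), baseline removed.
#' @param fs Sampling frequency (Hz).
#' @param refractory_s Minimum beat separation in seconds (default 0.2).
#' @return Integer vector of beat sample indices (possibly empty).
#' @export
detect_qrs <- function(signal, fs, refractory_s = 0.2) {
  n <- length(signal)
  if (n < fs) return(integer())
  if (max(signal) == min(signal)) return(integer())

  bp <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  f <- signal::filtfilt(bp, signal)
  e <- (c(0, diff(f)) * fs)^2
  k <- odd_window(0.10 * fs)
  env <- stats::filter(e, rep(1 / k, k), sides = 2)
  env[is.na(env)] <- 0
  env <- as.numeric(env)

  # candidate local maxima of the envelope
  cand <- which(diff(sign(diff(env))) < 0) + 1L
  cand <- cand[env[cand] > 0]
  if (!length(cand)) return(integer())

  init <- env[seq_len(min(n, as.integer(2 * fs)))]
  spk <- max(init) * 0.75
  npk <- mean(init) * 0.5
  thr <- npk + 0.25 * (spk - npk)
  refr <- refractory_s * fs

  beats <- integer()
  last <- -Inf
  for (i in cand) {
    v <- env[i]
    if (v > thr && (i - last) >= refr) {
      beats <- c(beats, i)
      last <- i
      spk <- 0.125 * v + 0.875 * spk
    } else if (v <= thr) {
      npk <- 0.125 * v + 0.875 * npk
    }
    thr <- npk + 0.25 * (spk - npk)
  }
  beats
}

#' Snap beats to the local absolute-amplitude maximum
#'
#' Moves every beat to the sample of maximum `|signal|` within
#' `+/- radius_ms` of its current position, so beat times sit exactly on the
#' dominant QRS deflection. Beats near the record edge are clamped to the
#' valid range. With beats already on an extremum the operation is a no-op.
#'
#' @param signal Numeric vector (mV).
#' @param beats Integer vector of beat sample indices.
#' @param fs Sampling frequency (Hz).
#' @param radius_ms Search radius (default 50 ms; keep below half the
#'   detector's refractory period).
#' @return Integer vector of refined beat indices, same length.
#' @export
refine_qrs <- function(signal, beats, fs, radius_ms = 50) {
  if (!length(beats)) return(integer())
  n <- length(signal)
  r <- max(1L, as.integer(round(radius_ms / 1000 * fs)))
  beats <- pmin(pmax(as.integer(beats), 1L), n)
  vapply(beats, function(b) {
    lo <- max(1L, b - r); hi <- min(n, b + r)
    w <- abs(signal[lo:hi])
    lo + which.max(w) - 1L
  }, integer(1))
}

#' Derive an RR-interval table from beat samples
#'
#' Converts beat sample indices to a per-beat table of RR intervals,
#' `rr_s[i] = (beat[i+1] - beat[i]) / fs`. Beats falling in unusable quality
#' windows are dropped first; an interval is marked non-contiguous when a
#' dropped beat lies between its endpoints or the span crosses an unusable
#' window, so no screening window straddles the gap.
#'
#' @param beats Strictly increasing integer sample indices.
#' @param fs Sampling frequency (Hz).
#' @param quality Optional `quality_mask` from [assess_quality()].
#' @return A per-beat tibble `beat`, `sample`, `time_s`, `rr_s`,
#'   `contiguous` (both `NA` on the last beat); empty when fewer than 2
#'   usable beats remain.
#' @export
rr_from_beats <- function(beats, fs, quality = NULL) {
  if (is.unsorted(beats, strictly = TRUE))
    abort("`beats` must be strictly increasing.")
  beats <- as.integer(beats)
  ok <- sample_usable(beats, quality)
  kept <- beats[ok]
  if (length(kept) < 2L) {
    return(tibble(beat = integer(), sample = integer(), time_s = numeric(),
                  rr_s = numeric(), contiguous = logical()))
  }
  kept_pos <- which(ok)
  m <- length(kept)
  rr <- diff(kept) / fs
  # adjacency in the original beat list
  adjacent <- diff(kept_pos) == 1L
  clean_span <- if (is.null(quality) || nrow(quality) == 0L) {
    rep(TRUE, m - 1L)
  } else {
    win <- as.integer(round(attr(quality, "window_s") * attr(quality, "fs")))
    w_of <- function(s) pmin(nrow(quality), (s - 1L) %/% win + 1L)
    vapply(seq_len(m - 1L), function(i) {
      all(quality$usable[w_of(kept[i]):w_of(kept[i + 1L])])
    }, logical(1))
  }
  tibble(
    beat = seq_len(m),
    sample = kept,
    time_s = kept / fs,
    rr_s = c(rr, NA_real_),
    contiguous = c(adjacent & clean_span, NA))
}
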