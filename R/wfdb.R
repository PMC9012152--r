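# Minimal WFDB (PhysioNet waveform-database) support: header + signal formats
# 16 (read/write) and 212 (read), and the MIT annotation codec with rhythm
# (aux) strings. Covers the subset used by mitdb/afdb-style records.

# annotation code number -> mnemonic symbol
WFDB_SYMBOLS <- c(
  "1" = "N", "2" = "L", "3" = "R", "4" = "a", "5" = "V", "6" = "F",
  "7" = "J", "8" = "A", "9" = "S", "10" = "E", "11" = "j", "12" = "/",
  "13" = "Q", "14" = "~", "16" = "|", "18" = "s", "19" = "T", "20" = "*",
  "21" = "D", "22" = "\"", "23" = "=", "24" = "p", "25" = "B", "26" = "^",
  "27" = "t", "28" = "+", "29" = "u", "30" = "?", "31" = "!", "32" = "[",
  "33" = "]", "34" = "e", "35" = "n", "36" = "@", "37" = "x", "38" = "f",
  "39" = "(", "40" = ")", "41" = "r")

symbol_to_code <- function(symbol) {
  codes <- as.integer(names(WFDB_SYMBOLS))
  out <- codes[match(symbol, WFDB_SYMBOLS)]
  if (anyNA(out))
    abort(sprintf("unknown annotation symbol(s): %s",
                  paste(unique(symbol[is.na(out)]), collapse = " ")))
  out
}

# symbols that mark beats (as opposed to rhythm/quality/non-beat events)
BEAT_SYMBOLS <- c("N", "L", "R", "a", "V", "F", "J", "A", "S", "E", "j",
                  "/", "Q", "e", "n", "f", "r", "!", "B")

# documented rhythm labels; others are preserved but flagged
KNOWN_RHYTHMS <- c("AFIB", "AFL", "J", "N")

#' Read a WFDB record
#'
#' Reads a `.hea` header, its signal file(s) (formats 16 and 212) and, when
#' present, a `.atr` annotation file. Signals are returned in physical units
#' (mV). Beat annotations become `beat_samples`/`beat_codes`; rhythm-change
#' annotations (`+` with an aux string such as `(AFIB`) become
#' `rhythm_intervals`. Unknown rhythm labels are kept and reported with a
#' warning.
#'
#' @param path Record path prefix (no extension), e.g. `"data/100"`.
#' @param annotator Annotation file extension (default `"atr"`).
#' @return A `wfdb_record`: list with `signal` (samples x leads matrix, mV),
#'   `fs`, `beat_samples`, `beat_codes`, `rhythm_intervals` (tibble
#'   `start_sample`, `rhythm_label`), `record_name`.
#' @export
read_record <- function(path, annotator = "atr") {
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) abort(sprintf("header file not found: %s", hea))
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  record_name <- sub("/.*$", "", rec[1])
  n_sig <- as.integer(rec[2])
  fs <- if (length(rec) >= 3) as.numeric(sub("/.*$", "", rec[3])) else 250
  n_samp <- if (length(rec) >= 4) as.integer(rec[4]) else NA_integer_

  sig_lines <- lines[seq_len(n_sig) + 1L]
  sig_info <- map(sig_lines, parse_signal_line)
  dat_file <- sig_info[[1]]$file
  if (!all(map_chr(sig_info, "file") == dat_file))
    abort("multi-file records are not supported.")
  fmt <- sig_info[[1]]$format
  dat_path <- file.path(dirname(hea), dat_file)
  if (!file.exists(dat_path))
    abort(sprintf("signal file not found: %s", dat_path))

  adc <- read_dat(dat_path, fmt, n_sig)
  if (!is.na(n_samp) && nrow(adc) > n_samp) adc <- adc[seq_len(n_samp), ,
                                                       drop = FALSE]
  phys <- sapply(seq_len(n_sig), function(j) {
    info <- sig_info[[j]]
    (adc[, j] - info$baseline) / info$gain
  })
  if (!is.matrix(phys)) phys <- matrix(phys, ncol = n_sig)

  ann_path <- paste0(path, ".", annotator)
  beat_samples <- integer()
  beat_codes <- character()
  rhythm <- tibble(start_sample = integer(), rhythm_label = character())
  if (file.exists(ann_path)) {
    ann <- read_annotations(ann_path)
    is_beat <- ann$symbol %in% BEAT_SYMBOLS
    beat_samples <- ann$sample[is_beat]
    beat_codes <- ann$symbol[is_beat]
    is_rhythm <- ann$symbol == "+"
    if (any(is_rhythm)) {
      lab <- sub("^\\(", "", ann$aux[is_rhythm])
      unknown <- setdiff(unique(lab), KNOWN_RHYTHMS)
      if (length(unknown))
        warn(sprintf("unknown rhythm label(s) retained: %s",
                     paste(unknown, collapse = ", ")))
      rhythm <- tibble(start_sample = ann$sample[is_rhythm],
                       rhythm_label = lab)
    }
  }

  structure(
    list(signal = phys, fs = fs, record_name = record_name,
         beat_samples = beat_samples, beat_codes = beat_codes,
         rhythm_intervals = rhythm),
    class = "wfdb_record")
}

#' @export
print.wfdb_record <- function(x, ...) {
  cat(sprintf("<wfdb_record> %s: %d samples x %d lead(s) at %g Hz, %d beats\n",
              x$record_name, nrow(x$signal), ncol(x$signal), x$fs,
              length(x$beat_samples)))
  invisible(x)
}

parse_signal_line <- function(line) {
  f <- strsplit(trimws(line), "\\s+")[[1]]
  fmt <- as.integer(sub("x.*$|:.*$|\\+.*$", "", f[2]))
  gain_spec <- if (length(f) >= 3) f[3] else "200"
  gain <- as.numeric(sub("\\(.*$", "", sub("/.*$", "", gain_spec)))
  if (is.na(gain) || gain == 0) gain <- 200
  baseline <- if (grepl("\\(", gain_spec)) {
    as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_spec))
  } else if (length(f) >= 5) as.numeric(f[5]) else 0
  if (is.na(baseline)) baseline <- 0
  list(file = f[1], format = fmt, gain = gain, baseline = baseline)
}

read_dat <- function(path, fmt, n_sig) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (fmt == 16L) {
    vals <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                    signed = TRUE, endian = "little")
    n_frame <- length(vals) %/% n_sig
    matrix(vals[seq_len(n_frame * n_sig)], ncol = n_sig, byrow = TRUE)
  } else if (fmt == 212L) {
    b <- as.integer(raw)
    n_pair <- length(b) %/% 3L
    i <- seq_len(n_pair) * 3L - 2L
    s1 <- b[i] + bitwShiftL(bitwAnd(b[i + 1L], 0x0F), 8)
    s2 <- b[i + 2L] + bitwShiftL(bitwAnd(b[i + 1L], 0xF0), 4)
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    vals <- as.integer(rbind(s1, s2))
    n_frame <- length(vals) %/% n_sig
    matrix(vals[seq_len(n_frame * n_sig)], ncol = n_sig, byrow = TRUE)
  } else {
    abort(sprintf("unsupported WFDB signal format: %d", fmt))
  }
}

#' Write a WFDB record
#'
#' Writes a single- or multi-lead signal as a format-16 WFDB record (header +
#' signal file) and, when beats are given, a MIT-format annotation file.
#'
#' @param path Record path prefix (no extension).
#' @param signal Numeric vector or samples-x-leads matrix, physical mV.
#' @param fs Sampling frequency (Hz).
#' @param beat_samples,beat_codes Optional beat annotations (sample indices,
#'   mnemonic symbols).
#' @param rhythm_intervals Optional tibble `start_sample`, `rhythm_label`;
#'   written as `+` annotations with `(LABEL` aux strings.
#' @param gain ADC units per mV (default 200).
#' @param annotator Annotation extension (default `"atr"`).
#' @return `path`, invisibly.
#' @export
write_record <- function(path, signal, fs, beat_samples = NULL,
                         beat_codes = NULL, rhythm_intervals = NULL,
                         gain = 200, annotator = "atr") {
  if (is.vector(signal)) signal <- matrix(signal, ncol = 1)
  n_sig <- ncol(signal)
  n_samp <- nrow(signal)
  name <- basename(path)
  adc <- round(signal * gain)
  adc <- pmin(pmax(adc, -32768), 32767)

  hea <- c(sprintf("%s %d %g %d", name, n_sig, fs, n_samp),
           sprintf("%s.dat 16 %g(0)/mV 16 0 %d 0 0 lead%d",
                   name, gain, as.integer(adc[1, ]), seq_len(n_sig)))
  writeLines(hea, paste0(path, ".hea"))
  writeBin(as.integer(t(adc)), paste0(path, ".dat"), size = 2L,
           endian = "little")

  if (!is.null(beat_samples) || !is.null(rhythm_intervals)) {
    samples <- c(if (!is.null(beat_samples)) as.integer(beat_samples),
                 if (!is.null(rhythm_intervals))
                   as.integer(rhythm_intervals$start_sample))
    symbols <- c(if (!is.null(beat_samples)) beat_codes,
                 if (!is.null(rhythm_intervals))
                   rep("+", nrow(rhythm_intervals)))
    aux <- c(if (!is.null(beat_samples)) rep(NA_character_,
                                             length(beat_samples)),
             if (!is.null(rhythm_intervals))
               paste0("(", rhythm_intervals$rhythm_label))
    o <- order(samples)
    write_annotations(paste0(path, ".", annotator),
                      samples[o], symbols[o], aux[o])
  }
  invisible(path)
}

#' Read / write a MIT-format annotation file
#'
#' Low-level codec for `.atr`-style files: 16-bit little-endian words with a
#' 6-bit type code and 10-bit time increment, plus SKIP (long intervals) and
#' AUX (attached strings, e.g. rhythm labels) pseudo-codes.
#'
#' @param path Annotation file path.
#' @return `read_annotations()`: tibble `sample`, `code`, `symbol`, `aux`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  raw <- readBin(path, "raw", n = file.size(path))
  n_words <- length(raw) %/% 2L
  sample <- integer(); code <- integer(); aux <- character()
  t_now <- 0
  i <- 1L  # byte cursor
  word_at <- function(i) {
    as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  }
  last_ann <- 0L
  while (i + 1L <= length(raw)) {
    w <- word_at(i); i <- i + 2L
    cd <- bitwShiftR(w, 10L)
    tm <- bitwAnd(w, 1023L)
    if (cd == 0L && tm == 0L) break             # EOF
    if (cd == 59L) {                             # SKIP: 32-bit interval
      hi <- word_at(i); lo <- word_at(i + 2L); i <- i + 4L
      t_now <- t_now + hi * 65536 + lo
    } else if (cd == 63L) {                      # AUX bytes attach to the
      nb <- tm                                   # previous annotation
      bytes <- raw[i:(i + nb - 1L)]
      s <- rawToChar(bytes[bytes != as.raw(0L)])
      if (last_ann > 0L) aux[last_ann] <- s
      i <- i + nb + (nb %% 2L)
    } else if (cd %in% c(60L, 61L, 62L)) {       # NUM/SUB/CHN modifiers
      next
    } else {
      t_now <- t_now + tm
      sample <- c(sample, as.integer(t_now))
      code <- c(code, cd)
      aux <- c(aux, NA_character_)
      last_ann <- length(sample)
    }
  }
  tibble(sample = sample, code = code,
         symbol = unname(WFDB_SYMBOLS[as.character(code)]),
         aux = aux)
}

#' @rdname read_annotations
#' @param sample Strictly increasing annotation sample indices.
#' @param symbol Mnemonic symbols (see `WFDB_SYMBOLS`).
#' @param aux Optional per-annotation aux strings (`NA` for none).
#' @export
write_annotations <- function(path, sample, symbol, aux = NULL) {
  if (is.unsorted(sample)) abort("`sample` must be sorted.")
  code <- symbol_to_code(symbol)
  if (is.null(aux)) aux <- rep(NA_character_, length(sample))
  con <- file(path, "wb")
  on.exit(close(con))
  putw <- function(w) writeBin(as.integer(w), con, size = 2L,
                               endian = "little")
  t_prev <- 0
  for (k in seq_along(sample)) {
    delta <- sample[k] - t_prev
    t_prev <- sample[k]
    if (delta > 1023 || delta < 0) {
      putw(bitwShiftL(59L, 10L))
      putw(delta %/% 65536)
      putw(delta %% 65536)
      delta <- 0
    }
    putw(bitwShiftL(code[k], 10L) + delta)
    if (!is.na(aux[k]) && nzchar(aux[k])) {
      bytes <- charToRaw(aux[k])
      putw(bitwShiftL(63L, 10L) + length(bytes))
      writeBin(bytes, con)
      if (length(bytes) %% 2L == 1L) writeBin(as.raw(0L), con)
    }
  }
  putw(0L)
  invisible(path)
}

#' Map WFDB beat symbols to the N / PB / OTHER classes
#'
#' Premature beats (atrial `A`, aberrated atrial `a`, nodal `J`, ventricular
#' `V`, and ventricular fusion `F` by default) map to `PB`; normal and the
#' remaining supraventricular/escape beats map to `N`; paced, unknown and
#' unrecognised symbols map to `OTHER` (reported via a message).
#'
#' @param beat_codes Character vector of beat symbols.
#' @param pb_codes Symbols counted as premature (configurable).
#' @return Character vector over `{"N", "PB", "OTHER"}`.
#' @examples
#' map_beat_codes(c("N", "V", "N"))
#' @export
map_beat_codes <- function(beat_codes,
                           pb_codes = c("A", "a", "J", "V", "F")) {
  n_codes <- setdiff(BEAT_SYMBOLS, c(pb_codes, "/", "Q", "f"))
  out <- ifelse(beat_codes %in% pb_codes, "PB",
                ifelse(beat_codes %in% n_codes, "N", "OTHER"))
  unknown <- unique(beat_codes[out == "OTHER"])
  if (length(unknown))
    inform(sprintf("beat symbol(s) mapped to OTHER: %s",
                   paste(unknown, collapse = " ")))
  out
}

#' Extract 31-beat premature-beat test segments from an annotated record
#'
#' Every premature beat with at least 15 annotated beats on each side yields
#' a 31-beat (30-RR) window centred on it; windows whose centre beat was
#' already covered by an earlier window are skipped (deduplication), and
#' windows overlapping an AFIB rhythm interval are discarded since AF beats
#' are excluded from the non-PB class. Each window is categorised from its
#' beat-code pattern string (`*` = PB, `N` = other): bigeminy when it
#' contains `*N*N*N` or `N*N*N*`; else trigeminy when it contains `*NN*NN`,
#' `N*NN*N` or `NN*NN*`; else multi-PB when it holds two or more PBs; else
#' single-PB.
#'
#' @param record A `wfdb_record` with beats annotated.
#' @param margin Beats required on each side of a PB (default 15).
#' @inheritParams map_beat_codes
#' @return A tibble: `record`, `center_beat`, `start_beat`, `category`, and
#'   list columns `rr` (30 intervals, seconds) and `codes` (31 symbols).
#' @export
extract_pb_segments <- function(record, margin = 15L,
                                pb_codes = c("A", "a", "J", "V", "F")) {
  stopifnot(inherits(record, "wfdb_record"))
  n <- length(record$beat_samples)
  if (n == 0L) abort("record has no beat annotations.")
  mapped <- suppressMessages(map_beat_codes(record$beat_codes, pb_codes))
  af_beat <- beats_in_af(record$beat_samples, record$rhythm_intervals)

  pb_idx <- which(mapped == "PB")
  segs <- list()
  covered_until <- 0L
  n_af_dropped <- 0L
  for (p in pb_idx) {
    if (p <= covered_until) next       # centre already inside a kept window
    if (p - margin < 1L || p + margin > n) next
    idx <- (p - margin):(p + margin)
    if (any(af_beat[idx])) {
      n_af_dropped <- n_af_dropped + 1L
      next
    }
    pat <- paste(ifelse(mapped[idx] == "PB", "*", "N"), collapse = "")
    n_pb <- sum(mapped[idx] == "PB")
    category <- if (grepl("*N*N*N", pat, fixed = TRUE) ||
                    grepl("N*N*N*", pat, fixed = TRUE)) {
      "BIGEMINY"
    } else if (grepl("*NN*NN", pat, fixed = TRUE) ||
               grepl("N*NN*N", pat, fixed = TRUE) ||
               grepl("NN*NN*", pat, fixed = TRUE)) {
      "TRIGEMINY"
    } else if (n_pb >= 2L) "MULTI_PB" else "SINGLE_PB"
    rr_w <- diff(record$beat_samples[idx]) / record$fs
    codes_w <- record$beat_codes[idx]
    segs[[length(segs) + 1L]] <- tibble(
      record = record$record_name,
      center_beat = p,
      start_beat = p - margin,
      category = category,
      rr = list(rr_w),
      codes = list(codes_w))
    covered_until <- p + margin
  }
  if (n_af_dropped > 0L)
    inform(sprintf("%d window(s) overlapping AF rhythm discarded.",
                   n_af_dropped))
  if (length(segs)) list_rbind(segs) else
    tibble(record = character(), center_beat = integer(),
           start_beat = integer(), category = character(),
           rr = list(), codes = list())
}

beats_in_af <- function(beat_samples, rhythm_intervals) {
  if (is.null(rhythm_intervals) || nrow(rhythm_intervals) == 0L)
    return(rep(FALSE, length(beat_samples)))
  lab <- rhythm_label_at(beat_samples, rhythm_intervals)
  lab == "AFIB"
}

# rhythm label in force at each sample (beats before the first annotation
# take the first interval's label)
rhythm_label_at <- function(samples, rhythm_intervals) {
  ri <- arrange(rhythm_intervals, .data$start_sample)
  idx <- findInterval(samples, ri$start_sample)
  idx[idx == 0L] <- 1L
  ri$rhythm_label[idx]
}

#' Per-beat AF / non-AF rhythm segments from rhythm annotations
#'
#' Labels every annotated beat AF when it falls inside an `AFIB` rhythm
#' interval (atrial flutter and junctional rhythm count as non-AF) and
#' returns maximal runs of same-label beats as half-open beat-index
#' segments, each anchored on QRS beats. Beats preceding the first rhythm
#' annotation inherit the first interval's label.
#'
#' @param record A `wfdb_record` with beats and rhythm intervals.
#' @return A tibble `start`, `end`, `label` with `label` in `{"AF", "N"}`.
#' @export
rhythm_segments_from_annotations <- function(record) {
  stopifnot(inherits(record, "wfdb_record"))
  if (nrow(record$rhythm_intervals) == 0L)
    abort("record has no rhythm annotations.")
  if (length(record$beat_samples) == 0L)
    abort("record has no beat annotations.")
  lab <- ifelse(beats_in_af(record$beat_samples, record$rhythm_intervals),
                "AF", "N")
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  tibble(start = ends - r$lengths + 1L, end = ends + 1L, label = r$values)
}
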