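make_test_record <- function(dir, name = "rec01", seed = 17, n_beats = 60,
                             rhythms = NULL) {
  rec <- gen_rr(rhythm_spec("NSR", n_beats, seed = seed))
  ecg <- render_ecg(rec, fs = 250, seed = seed)
  codes <- rep("N", n_beats)
  path <- file.path(dir, name)
  write_record(path, ecg$signal, fs = 250, beat_samples = ecg$true_qrs,
               beat_codes = codes, rhythm_intervals = rhythms)
  list(path = path, ecg = ecg, codes = codes)
}

test_that("WFDB records round-trip signal, beats and rhythm intervals", {
  dir <- withr::local_tempdir()
  rhythms <- tibble::tibble(start_sample = c(1L, 5000L),
                            rhythm_label = c("N", "AFIB"))
  made <- make_test_record(dir, rhythms = rhythms)
  rec <- read_record(made$path)
  expect_s3_class(rec, "wfdb_record")
  expect_equal(rec$fs, 250)
  expect_identical(rec$beat_samples, made$ecg$true_qrs)
  expect_identical(rec$beat_codes, made$codes)
  expect_equal(rec$rhythm_intervals$start_sample, rhythms$start_sample)
  expect_equal(rec$rhythm_intervals$rhythm_label, rhythms$rhythm_label)
  # format-16 quantisation at gain 200 is 5 microvolt
  expect_lt(max(abs(rec$signal[, 1] - made$ecg$signal)), 1 / 200)
})

test_that("records without annotations read with empty rhythm intervals", {
  dir <- withr::local_tempdir()
  rec0 <- gen_rr(rhythm_spec("NSR", 20, seed = 2))
  ecg <- render_ecg(rec0, fs = 250)
  write_record(file.path(dir, "bare"), ecg$signal, fs = 250)
  rec <- read_record(file.path(dir, "bare"))
  expect_length(rec$beat_samples, 0)
  expect_equal(nrow(rec$rhythm_intervals), 0)
  expect_error(read_record(file.path(dir, "missing")), "missing")
})

test_that("annotation codec handles long gaps, aux strings and odd lengths", {
  f <- withr::local_tempfile(fileext = ".atr")
  # gap of 200000 samples forces the 32-bit SKIP path; aux strings include
  # odd byte counts (pad byte required)
  samples <- c(10L, 250L, 200250L, 200500L)
  symbols <- c("+", "N", "+", "V")
  aux <- c("(N", NA, "(AFIB", NA)
  write_annotations(f, samples, symbols, aux)
  back <- read_annotations(f)
  expect_equal(back$sample, samples)
  expect_equal(back$symbol, symbols)
  expect_equal(back$aux, aux)
  expect_error(write_annotations(f, c(5L, 1L), c("N", "N")), "sorted")
  expect_error(write_annotations(f, 1L, "Z"), "unknown")
})

test_that("beat code mapping follows the premature-beat table", {
  expect_identical(map_beat_codes(c("N", "V", "N")), c("N", "PB", "N"))
  expect_identical(map_beat_codes(c("N", "N", "N")), c("N", "N", "N"))
  expect_identical(map_beat_codes(c("N", "A", "a", "J")),
                   c("N", "PB", "PB", "PB"))
  expect_message(out <- map_beat_codes(c("/", "Q")), "OTHER")
  expect_identical(out, c("OTHER", "OTHER"))
  # custom table
  expect_identical(map_beat_codes("S", pb_codes = "S"), "PB")
})

pb_record <- function(dir, codes, seed = 23, rhythms = NULL) {
  n <- length(codes)
  rec <- gen_rr(rhythm_spec("NSR", n, seed = seed))
  ecg <- render_ecg(rec, fs = 250, seed = seed)
  path <- file.path(dir, "pb")
  write_record(path, ecg$signal, fs = 250, beat_samples = ecg$true_qrs,
               beat_codes = codes, rhythm_intervals = rhythms)
  read_record(path)
}

test_that("premature-beat segments are extracted as centred 31-beat windows", {
  dir <- withr::local_tempdir()
  codes <- rep("N", 60); codes[30] <- "V"
  segs <- extract_pb_segments(pb_record(dir, codes))
  expect_equal(nrow(segs), 1)
  expect_equal(segs$category, "SINGLE_PB")
  expect_equal(segs$center_beat, 30)
  expect_equal(segs$start_beat, 15)
  expect_length(segs$rr[[1]], 30)
  expect_length(segs$codes[[1]], 31)

  # PB too close to the record edge yields no segment
  codes_edge <- rep("N", 40); codes_edge[5] <- "V"
  expect_equal(nrow(extract_pb_segments(pb_record(dir, codes_edge))), 0)
})

test_that("pattern strings assign bigeminy / trigeminy / multi categories", {
  dir <- withr::local_tempdir()
  codes <- rep("N", 61)
  codes[seq(24, 38, by = 2)] <- "V"     # alternating run inside the window
  segs <- extract_pb_segments(pb_record(dir, codes))
  expect_true(all(segs$category == "BIGEMINY"))

  codes <- rep("N", 61)
  codes[seq(24, 39, by = 3)] <- "V"     # every third beat
  segs <- extract_pb_segments(pb_record(dir, codes))
  expect_true(all(segs$category == "TRIGEMINY"))

  codes <- rep("N", 61)
  codes[c(25, 36)] <- "V"               # two isolated PBs, no pattern
  segs <- extract_pb_segments(pb_record(dir, codes))
  expect_equal(segs$category[1], "MULTI_PB")

  # categories re-derivable from the stored codes
  for (i in seq_len(nrow(segs))) {
    pat <- paste(ifelse(map_beat_codes(segs$codes[[i]]) == "PB", "*", "N"),
                 collapse = "")
    expect_equal(grepl("*N*N*N", pat, fixed = TRUE) ||
                 grepl("N*N*N*", pat, fixed = TRUE), FALSE)
  }
})

test_that("windows overlapping AF rhythm are discarded", {
  dir <- withr::local_tempdir()
  codes <- rep("N", 60); codes[30] <- "V"
  rec_af <- pb_record(dir, codes,
                      rhythms = tibble::tibble(start_sample = 1L,
                                               rhythm_label = "AFIB"))
  expect_message(segs <- extract_pb_segments(rec_af), "discarded")
  expect_equal(nrow(segs), 0)
})

test_that("rhythm segments follow the AFIB intervals on beat anchors", {
  dir <- withr::local_tempdir()
  made <- make_test_record(dir, n_beats = 60)
  rec <- read_record(made$path)
  b <- rec$beat_samples
  rhythms <- tibble::tibble(start_sample = c(1L, b[21], b[41]),
                            rhythm_label = c("N", "AFIB", "N"))
  write_record(made$path, rec$signal[, 1], fs = 250, beat_samples = b,
               beat_codes = rec$beat_codes, rhythm_intervals = rhythms)
  segs <- rhythm_segments_from_annotations(read_record(made$path))
  expect_equal(segs$label, c("N", "AF", "N"))
  expect_equal(segs$start[2], 21L)
  expect_equal(segs$end[2], 41L)

  # atrial flutter counts as non-AF
  rhythms$rhythm_label <- c("N", "AFL", "N")
  write_record(made$path, rec$signal[, 1], fs = 250, beat_samples = b,
               beat_codes = rec$beat_codes, rhythm_intervals = rhythms)
  segs <- rhythm_segments_from_annotations(read_record(made$path))
  expect_equal(unique(segs$label), "N")

  # all-AFIB record gives one segment covering every beat
  write_record(made$path, rec$signal[, 1], fs = 250, beat_samples = b,
               beat_codes = rec$beat_codes,
               rhythm_intervals = tibble::tibble(start_sample = 1L,
                                                 rhythm_label = "AFIB"))
  segs <- rhythm_segments_from_annotations(read_record(made$path))
  expect_equal(nrow(segs), 1)
  expect_equal(segs$end - segs$start, 60L)
})
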