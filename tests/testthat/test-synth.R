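test_that("NSR generation is low-variability with no premature labels", {
  b <- gen_rr(rhythm_spec("NSR", n_beats = 31, seed = 1))
  rr <- b$rr_s[!is.na(b$rr_s)]
  expect_equal(nrow(b), 31)
  expect_length(rr, 30)
  expect_lt(sd(rr) / mean(rr), 0.05)
  expect_true(all(b$beat_label == "N"))
})

test_that("bigeminy alternates coupling and compensatory intervals", {
  b <- gen_rr(rhythm_spec("BIGEMINY", n_beats = 31, seed = 3))
  rr <- b$rr_s[!is.na(b$rr_s)]
  short <- rr[seq(1, 29, by = 2)]
  long <- rr[seq(2, 30, by = 2)]
  expect_true(all(abs(short - 0.48) < 0.1))
  expect_true(all(abs(long - 1.12) < 0.15))
  # alternation holds over at least 6 consecutive beats by construction
  expect_true(all(short[1:14] < long[1:14]))
  expect_identical(which(b$beat_label == "PB"), seq(2L, 30L, by = 2L))
})

test_that("trigeminy repeats short/long/normal and labels every third beat", {
  b <- gen_rr(rhythm_spec("TRIGEMINY", n_beats = 31, seed = 4))
  rr <- b$rr_s[!is.na(b$rr_s)]
  expect_true(all(rr[seq(1, 28, by = 3)] < 0.6))   # couplings
  expect_true(all(rr[seq(2, 29, by = 3)] > 1.0))   # pauses
  expect_true(all(abs(rr[seq(3, 30, by = 3)] - 0.8) < 0.15))
  expect_identical(which(b$beat_label == "PB"), seq(2L, 29L, by = 3L))
})

test_that("a single premature beat sits away from the edges with the
           coupling/pause signature", {
  for (seed in 1:20) {
    b <- gen_rr(rhythm_spec("SINGLE_PB", n_beats = 31, seed = seed))
    p <- which(b$beat_label == "PB")
    expect_length(p, 1)
    expect_gt(p, 3)
    expect_lte(p, 28)
    expect_lt(b$rr_s[p - 1], 0.8)   # coupling shorter than base
    expect_gt(b$rr_s[p], 0.8)       # pause longer than base
  }
})

test_that("multi-PB placements respect the count and minimum spacing", {
  for (seed in 1:20) {
    b <- gen_rr(rhythm_spec("MULTI_PB", n_beats = 31, n_pb = 4, seed = seed))
    p <- which(b$beat_label == "PB")
    expect_length(p, 4)
    expect_true(all(diff(p) >= 3))
    expect_true(all(b$rr_s[p - 1] < 0.8) && all(b$rr_s[p] > 0.8))
  }
})

test_that("generated intervals stay inside the physiological bounds", {
  for (cl in c("NSR", "AF", "SINGLE_PB", "MULTI_PB", "BIGEMINY",
               "TRIGEMINY")) {
    b <- gen_rr(rhythm_spec(cl, n_beats = 100, seed = 11))
    rr <- b$rr_s[!is.na(b$rr_s)]
    expect_true(all(rr >= 0.2 & rr <= 2.5), label = cl)
  }
})

test_that("AF draws hit the requested coefficient of variation", {
  b <- gen_rr(rhythm_spec("AF", n_beats = 250, seed = 5))
  rr <- b$rr_s[!is.na(b$rr_s)]
  cv <- sd(rr) / mean(rr)
  expect_gt(cv, 0.20 * 0.7)
  expect_lt(cv, 0.20 * 1.3)
})

test_that("a fixed seed reproduces the draw exactly", {
  s <- rhythm_spec("AF", n_beats = 50, seed = 99)
  expect_identical(gen_rr(s), gen_rr(s))
  rec_spec <- list(list(spec = rhythm_spec("NSR", 20), label = "N"),
                   list(spec = rhythm_spec("AF", 20), label = "AFIB"))
  expect_identical(gen_recording(rec_spec, seed = 7),
                   gen_recording(rec_spec, seed = 7))
})

test_that("invalid spec fields are rejected with the field named", {
  expect_error(rhythm_spec("NSR", n_beats = 0), "n_beats")
  expect_error(rhythm_spec("NSR", base_rr = -1), "base_rr")
  expect_error(rhythm_spec("NSR", nsr_cv = 1.2), "nsr_cv")
  expect_error(rhythm_spec("NSR", coupling_fraction = 1.5),
               "coupling_fraction")
  expect_error(rhythm_spec("NSR", compensatory_fraction = 0.9),
               "compensatory_fraction")
  expect_error(gen_rr(rhythm_spec("NSR", n_beats = 5)), "n_beats")
})

test_that("recordings concatenate episodes with recoverable ground truth", {
  rec <- gen_recording(list(
    list(spec = rhythm_spec("NSR", 100), label = "N"),
    list(spec = rhythm_spec("AF", 80), label = "AFIB"),
    list(spec = rhythm_spec("NSR", 100), label = "N")), seed = 2)
  expect_equal(nrow(rec$beats), 280)
  expect_equal(rec$annotation$start_beat, c(1L, 101L, 181L))
  segs <- recording_segments(rec)
  af <- segs[segs$label == "AFIB", ]
  expect_equal(af$start, 101L)
  expect_equal(af$end, 181L)

  one <- gen_recording(list(list(spec = rhythm_spec("NSR", 30), label = "N")),
                       seed = 1)
  expect_equal(one$annotation$start_beat, 1L)

  alt <- gen_recording(unlist(lapply(1:5, function(i) list(
    list(spec = rhythm_spec("NSR", 40), label = "N"),
    list(spec = rhythm_spec("AF", 40), label = "AFIB"))),
    recursive = FALSE), seed = 3)
  segs <- recording_segments(alt)
  expect_equal(sum(segs$label == "AFIB"), 5)
  expect_equal(segs$start[segs$label == "AFIB"], seq(41L, 361L, by = 80L))
  expect_error(gen_recording(list()), "non-empty")
})

test_that("rendered ECG places template maxima at the reported truth", {
  rec <- gen_rr(rhythm_spec("NSR", 31, seed = 6))
  ecg <- render_ecg(rec, fs = 250, noise_sd = 0, baseline_wander_amp = 0)
  # each true index is the absolute maximum in its neighbourhood
  refined <- refine_qrs(ecg$signal, ecg$true_qrs, ecg$fs)
  expect_identical(refined, ecg$true_qrs)
  # length arithmetic: padded duration at fs samples
  total <- max(rec$time_s) + 2 * 0.25
  expect_equal(length(ecg$signal), round(total * 250) + 1)
  expect_error(render_ecg(rec, fs = 50), "fs")
})

test_that("RR csv round-trips a recording", {
  rec <- gen_recording(list(
    list(spec = rhythm_spec("NSR", 20), label = "N"),
    list(spec = rhythm_spec("AF", 20), label = "AFIB")), seed = 8)
  f <- withr::local_tempfile(fileext = ".csv")
  write_rr_csv(rec, f)
  back <- read_rr_csv(f)
  expect_equal(back$beats$rr_s, rec$beats$rr_s, tolerance = 1e-12)
  expect_equal(back$annotation$rhythm_label, rec$annotation$rhythm_label)
  expect_error(read_rr_csv(tempfile()), "not found")
})
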