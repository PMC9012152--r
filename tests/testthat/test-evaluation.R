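test_that("segment score applies the three-beat tolerance rule", {
  L <- data.frame(start = 100, end = 200)
  expect_equal(segment_score(L, data.frame(start = 102, end = 199)), 1)
  # exactly 3 beats off: tolerance is strict, falls back to IoU
  expect_lt(segment_score(L, data.frame(start = 103, end = 200)), 1)
  expect_equal(segment_score(L, data.frame(start = 100, end = 200)), 1)
})

test_that("segment score falls back to beat IoU", {
  L <- data.frame(start = 1, end = 101)
  D <- data.frame(start = 51, end = 151)
  expect_equal(segment_score(L, D), 50 / 150)
  expect_equal(segment_score(L, data.frame(start = 300, end = 400)), 0)
  # fragmented detections never take the tolerance shortcut
  frag <- data.frame(start = c(1, 52), end = c(50, 101))
  expect_equal(segment_score(L, frag), (49 + 49) / 100)
})

test_that("segment score is shift invariant and overlap monotone", {
  L <- data.frame(start = 40, end = 90)
  D <- data.frame(start = 55, end = 120)
  s0 <- segment_score(L, D)
  for (off in c(-30, 17, 400)) {
    expect_equal(segment_score(
      data.frame(start = 40 + off, end = 90 + off),
      data.frame(start = 55 + off, end = 120 + off)), s0)
  }
  # growing |L n D| with |L u D| fixed never decreases the score
  scores <- sapply(0:14, function(g)
    segment_score(data.frame(start = 40, end = 90),
                  data.frame(start = 55 - g, end = 120)))
  expect_true(all(diff(scores) >= -1e-12))
})

test_that("recording score averages per-segment scores, misses count zero", {
  L <- data.frame(start = c(10, 100), end = c(50, 140))
  D <- data.frame(start = c(11, 200), end = c(49, 240))
  # first label matched within tolerance (1), second missed (0)
  expect_equal(recording_score(L, D), 0.5)
  expect_equal(recording_score(L, L), 1)
  expect_equal(recording_score(data.frame(start = 1, end = 10),
                               data.frame(start = 50, end = 60)), 0)
  expect_true(is.na(recording_score(data.frame(start = integer(),
                                               end = integer()), D)))
})

test_that("error and missed segment counts follow the overlap rules", {
  L <- data.frame(start = c(100, 300), end = c(200, 350))
  expect_equal(count_error_segments(L, data.frame(start = 120, end = 180)), 0)
  expect_equal(count_error_segments(L, data.frame(start = 210, end = 250)), 1)
  # detection straddling a boundary with >= 1 PAF beat is not an error
  expect_equal(count_error_segments(L, data.frame(start = 199, end = 260)), 0)
  expect_equal(count_missed_segments(L, data.frame(start = 120, end = 180)), 1)
  expect_equal(count_missed_segments(L, data.frame(start = c(120, 340),
                                                   end = c(180, 360))), 0)
  expect_equal(count_missed_segments(L, data.frame(start = integer(),
                                                   end = integer())), 2)
})

test_that("beat metrics form the expected confusion summaries", {
  L <- data.frame(start = 1, end = 51)    # beats 1..50 AF of 100
  same <- beat_metrics(L, L, 100)
  expect_equal(same$sensitivity, 1)
  expect_equal(same$specificity, 1)
  expect_equal(same$accuracy, 1)

  none <- beat_metrics(L, data.frame(start = integer(), end = integer()), 100)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 1)
  expect_equal(none$accuracy, 0.5)

  comp <- beat_metrics(L, data.frame(start = 51, end = 101), 100)
  expect_equal(comp$sensitivity, 0)
  expect_equal(comp$specificity, 0)

  # a class with no beats reports NA, not NaN
  all_af <- beat_metrics(data.frame(start = 1, end = 101), L, 100)
  expect_true(is.na(all_af$specificity))
})

test_that("the evaluation report ties the pieces together", {
  L <- data.frame(start = c(101, 300), end = c(181, 340))
  D <- data.frame(start = c(99, 500), end = c(183, 520))
  ev <- evaluate_detection(L, D, total_beats = 600)
  expect_s3_class(ev, "paf_eval")
  expect_equal(tidy(ev)$score, c(1, 0))
  expect_equal(ev$average_score, 0.5)
  expect_equal(ev$error_segments, 1)
  expect_equal(ev$missed_segments, 1)
  g <- glance(ev)
  expect_equal(g$n_labeled, 2)
  expect_equal(g$tp + g$fn, sum(L$end - L$start))
  expect_true(all(tidy(ev)$score >= 0 & tidy(ev)$score <= 1))
})

test_that("labels used as their own detections score perfectly", {
  set.seed(12)
  for (i in 1:10) {
    k <- sample(1:5, 1)
    starts <- sort(sample(seq(1, 900, by = 60), k))   # disjoint segments
    L <- data.frame(start = starts, end = starts + sample(5:40, k,
                                                          replace = TRUE))
    expect_equal(recording_score(L, L), 1)
    expect_equal(count_missed_segments(L, L), 0)
    expect_equal(count_error_segments(L, L), 0)
  }
})
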