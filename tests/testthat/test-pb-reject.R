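test_that("the run-length rule separates single ectopy from sustained change", {
  expect_true(single_pb_recheck(7))    # canonical single-PB footprint
  expect_true(single_pb_recheck(10))   # boundary: "exceeds" is strict
  expect_false(single_pb_recheck(11))
})

test_that("the median group recovers the normal beats of frequent ectopy", {
  rr <- gen_rr(rhythm_spec("MULTI_PB", 31, n_pb = 4, seed = 6))$rr_s
  rr <- rr[!is.na(rr)]
  cl <- cluster_rr(rr)
  sel <- select_median_group(cl)
  sel_rr <- cl$rr[cl$assignment == sel]
  expect_lt(abs(mean(sel_rr) - 0.8), 0.1)
  expect_gt(length(sel_rr), 15)   # normals dominate

  # pure arithmetic: means 0.5/0.8/1.1 with median near 0.78
  rr3 <- c(rep(0.5, 6), rep(0.8, 10), rep(1.1, 6))[sample(22)]
  withr::with_seed(1, {
    cl3 <- cluster_rr(c(rep(0.5, 6), rep(0.8, 10), rep(1.1, 6)))
  })
  expect_equal(cl3$group_means[select_median_group(cl3)], 0.8,
               tolerance = 0.05)
})

test_that("AF segments keep a variable near-median group", {
  set.seed(14)
  close_means <- replicate(30, {
    rr <- af_segment_rr(sample.int(1e6, 1))
    cl <- cluster_rr(rr)
    sel <- select_median_group(cl)
    abs(cl$group_means[sel] - mean(rr)) / mean(rr)
  })
  expect_lt(stats::median(close_means), 0.10)
})

test_that("the recheck demands every window at or below threshold", {
  expect_true(recheck_rc(rep(0.8, 20), threshold = 0.055))
  rr <- c(rep(0.8, 10), 1.6, rep(0.8, 9))
  expect_false(recheck_rc(rr, threshold = 0.055))
  # short selections carry no evidence under the default policy
  expect_false(recheck_rc(rep(0.8, 5)))
  expect_true(recheck_rc(rep(0.8, 5), short = "reject"))
})

test_that("the geminal pattern test counts balanced extreme groups", {
  set.seed(18)
  jit <- function(x) x * (1 + rnorm(length(x), 0, 0.01))
  # alternating short/long followed by normals: three genuine interval
  # populations, and the alternating windows hold 3 shorts + 3 longs.
  # (A pure bigeminy draw can legitimately split its shorts across two
  # clusters -- k = 3 on two populations -- in which case the pattern test
  # misses and the cascade rejects through the frequent-ectopy path; the
  # cascade-level tests below cover that.)
  rr_alt <- jit(c(rep(c(1.12, 0.48), 12), rep(0.8, 6)))
  cl_alt <- cluster_rr(rr_alt)
  expect_true(geminy_pattern_present(cl_alt))            # 3+3 windows
  expect_true(geminy_pattern_present(cl_alt, min_count = 2))

  # short/long/normal cycling: windows hold 2 short + 2 long, matched by
  # the permissive count, not by the strict default
  rr_tri <- jit(rep(c(0.48, 1.12, 0.8), 10))
  cl_tri <- cluster_rr(rr_tri)
  expect_true(geminy_pattern_present(cl_tri, min_count = 2))
  expect_false(geminy_pattern_present(cl_tri, min_count = 3))

  # 1 long + 5 short per window never balances
  lop <- withr::with_seed(4, cluster_rr(c(rep(0.5, 10), 1.3,
                                          rep(0.5, 10), 0.82)))
  expect_false(geminy_pattern_present(lop, min_count = 2))
})

test_that("geminal recheck rejects geminal rhythms, not AF", {
  set.seed(19)
  jit <- function(x) x * (1 + rnorm(length(x), 0, 0.01))
  cl_alt <- cluster_rr(jit(c(rep(c(1.12, 0.48), 12), rep(0.8, 6))))
  expect_true(geminy_recheck(cl_alt))

  cl_tri <- cluster_rr(jit(rep(c(0.48, 1.12, 0.8), 10)))
  expect_true(geminy_recheck(cl_tri))

  set.seed(31)
  kept <- mean(replicate(40, {
    cl_af <- cluster_rr(af_segment_rr(sample.int(1e6, 1)))
    !geminy_recheck(cl_af)
  }))
  expect_gte(kept, 0.9)
})

test_that("the cascade classifies each synthetic rhythm correctly", {
  classify_one <- function(cl_name, seed) {
    rr <- gen_rr(rhythm_spec(cl_name, 31, seed = seed))$rr_s
    rr <- rr[!is.na(rr)]
    s <- rc_series(rr)
    cands <- candidate_segments(s)
    if (nrow(cands) == 0) return("NONE")
    verdicts <- vapply(seq_len(nrow(cands)), function(i)
      classify_candidate(cands[i, ], rr)$klass, character(1))
    if (any(verdicts == "AF")) "AF" else verdicts[1]
  }
  expect_equal(classify_one("SINGLE_PB", 5), "SINGLE_PB")
  expect_equal(classify_one("BIGEMINY", 5), "GEMINY")
  # trigeminy is eliminated through the frequent-ectopy recheck under the
  # strict pattern count
  expect_true(classify_one("TRIGEMINY", 5) %in% c("MULTI_PB", "GEMINY"))
  expect_true(classify_one("MULTI_PB", 5) %in% c("MULTI_PB", "GEMINY",
                                                 "SINGLE_PB"))
  af <- mean(vapply(1:40, function(s) classify_one("AF", s) == "AF",
                    logical(1)))
  expect_gte(af, 0.9)
})

test_that("verdicts are deterministic and independent of candidate order", {
  rr <- c(gen_rr(rhythm_spec("AF", 31, seed = 3))$rr_s[1:30],
          rep(0.8, 20),
          gen_rr(rhythm_spec("AF", 31, seed = 4))$rr_s[1:30])
  s <- rc_series(rr)
  cands <- candidate_segments(s)
  expect_gte(nrow(cands), 2)
  v_fwd <- vapply(seq_len(nrow(cands)), function(i)
    classify_candidate(cands[i, ], rr, seed = 1)$klass, character(1))
  v_rev <- vapply(rev(seq_len(nrow(cands))), function(i)
    classify_candidate(cands[i, ], rr, seed = 1)$klass, character(1))
  expect_identical(v_fwd, rev(v_rev))
  expect_identical(v_fwd,
                   vapply(seq_len(nrow(cands)), function(i)
                     classify_candidate(cands[i, ], rr, seed = 1)$klass,
                     character(1)))
})
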