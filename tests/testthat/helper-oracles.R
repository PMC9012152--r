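# Independent oracles used across tests; deliberately naive implementations.

# Rc of one window: population (or sample) std over mean, written directly.
oracle_rc <- function(w, std_mode = "population") {
  m <- sum(w) / length(w)
  if (std_mode == "population") {
    sqrt(sum((w - m)^2) / length(w)) / m
  } else {
    sqrt(sum((w - m)^2) / (length(w) - 1)) / m
  }
}

# Per-beat Rc series by explicit per-window recomputation.
oracle_rc_series <- function(rr, std_mode = "population") {
  n <- length(rr)
  out <- rep(NA_real_, n + 1L)
  if (n >= 6L) {
    for (i in seq_len(n - 5L)) out[i] <- oracle_rc(rr[i:(i + 5L)], std_mode)
  }
  out
}

# Exhaustive k = 3 medoid cost on the same (unscaled) feature set the
# implementation clusters: (RR_i, (RR_i - RR_{i-1}) / RR_i).
oracle_kmedoids_cost <- function(rr) {
  feats <- cbind(rr, c(0, diff(rr)) / rr)
  d <- as.matrix(dist(feats))
  n <- length(rr)
  best <- Inf
  combos <- utils::combn(n, 3L)
  for (j in seq_len(ncol(combos))) {
    m <- combos[, j]
    best <- min(best, sum(pmin(d[, m[1]], d[, m[2]], d[, m[3]])))
  }
  best
}

# A constant-RR sequence with one premature pair (coupling + pause) inserted.
rr_with_pb <- function(n_rr = 30, base = 0.8, at = 15,
                       coupling = 0.6, compensatory = 1.4) {
  rr <- rep(base, n_rr)
  rr[at] <- coupling * base
  rr[at + 1] <- compensatory * base
  rr
}

af_segment_rr <- function(seed, n_beats = 31) {
  rr <- gen_rr(rhythm_spec("AF", n_beats, seed = seed))$rr_s
  rr[!is.na(rr)]
}
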