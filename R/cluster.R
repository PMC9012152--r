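#' Three-group K-medoids clustering of a segment's RR intervals
#'
#' Clusters the RR intervals of a suspected-AF segment into three groups using
#' two features per interval: the interval itself and the ratio of its
#' first-order difference to the interval (`(RR_i - RR_(i-1)) / RR_i`, 0 for
#' the first interval). Euclidean K-medoids (k = 3) runs on the features in
#' their natural units (seconds; dimensionless ratio). For premature-beat
#' rhythms the short coupling intervals, long pauses and normal intervals
#' separate cleanly in this plane; for AF no clear group structure exists
#' and the three group means stay close -- per-segment z-scoring
#' (`scale = "zscore"`) is available but tends to split AF segments into
#' artificial RR-value bands, which weakens the downstream rechecks.
#'
#' The medoid search is exact (exhaustive over all medoid triples) for
#' segments of up to `exact_max` intervals and a deterministic PAM-style
#' greedy build plus swap phase above that. A fine-tuning sweep then
#' reassigns individual intervals to the group of their second-nearest
#' medoid whenever that strictly lowers the pooled within-group sum of
#' squares of the raw RR values, so the within-group RR spread never
#' increases. One sweep (the default `ft_passes = 1`) corrects the boundary
#' misassignments K-medoids makes on structured ectopic rhythms; iterating
#' to convergence instead re-sorts diffuse AF segments into interval-value
#' bands and is deliberately not the default.
#'
#' @param rr Numeric vector of at least 6 strictly positive RR intervals
#'   (seconds), in temporal order.
#' @param seed Optional seed (the algorithm is deterministic; the seed only
#'   fixes tie-breaking in degenerate inputs).
#' @param exact_max Largest segment size for which the exhaustive medoid
#'   search is used (default 14).
#' @param fine_tune Run the within-group RR spread reduction pass
#'   (default `TRUE`).
#' @param scale Feature scaling before clustering: `"none"` (default,
#'   natural units) or `"zscore"` (per-segment standardisation).
#' @param ft_passes Maximum fine-tuning sweeps (default 1).
#' @return A `paf_cluster` object: list with `assignment` (group id per
#'   interval, 1..3 ordered by ascending group mean RR), `medoid_index`,
#'   `group_means`, `group_sizes`, `cost` (total feature-space distance to
#'   nearest medoid, before fine-tuning), `degenerate`, and the input `rr`.
#' @examples
#' rr <- gen_rr(rhythm_spec("BIGEMINY", 31, seed = 2))$rr_s
#' cluster_rr(rr[!is.na(rr)])
#' @export
cluster_rr <- function(rr, seed = NULL, exact_max = 14L, fine_tune = TRUE,
                       scale = c("none", "zscore"), ft_passes = 1L) {
  scale <- match.arg(scale)
  if (!is.numeric(rr) || length(rr) < 6L)
    abort("`rr` must hold at least 6 RR intervals.")
  if (anyNA(rr) || any(rr <= 0))
    abort("RR intervals must be strictly positive.")
  n <- length(rr)
  feats <- rr_features(rr)

  distinct <- unique(round(feats, 12))
  if (nrow(distinct) < 3L) {
    # Degenerate: group intervals by their (at most 2) distinct values.
    key <- apply(round(feats, 12), 1L, paste, collapse = "/")
    grp <- as.integer(factor(key, levels = unique(key)))
    grp <- order_groups_by_mean(grp, rr)
    return(new_paf_cluster(rr, grp, medoid_index = NA_integer_,
                           cost = NA_real_, degenerate = TRUE))
  }

  z <- if (scale == "zscore") scale_features(feats) else feats
  d <- as.matrix(stats::dist(z))

  med <- if (n <= exact_max) exact_medoids(d) else pam_medoids(d, k = 3L)
  assign0 <- nearest_medoid(d, med$medoids)
  grp <- order_groups_by_mean(assign0, rr)

  if (fine_tune) grp <- fine_tune_groups(grp, rr, d, med$medoids,
                                          max_passes = ft_passes)
  grp <- order_groups_by_mean(grp, rr)

  new_paf_cluster(rr, grp, medoid_index = med$medoids, cost = med$cost,
                  degenerate = FALSE)
}

rr_features <- function(rr) {
  drr <- c(0, diff(rr))
  cbind(rr = rr, rel_diff = drr / rr)
}

scale_features <- function(feats) {
  apply(feats, 2L, function(col) {
    s <- sd(col)
    if (!is.finite(s) || s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
}

# Exhaustive k = 3 medoid search on a distance matrix; first optimum in
# lexicographic order wins (deterministic).
exact_medoids <- function(d) {
  n <- nrow(d)
  triples <- utils::combn(n, 3L)
  best_cost <- Inf
  best <- NULL
  for (j in seq_len(ncol(triples))) {
    m <- triples[, j]
    cost <- sum(pmin(d[, m[1]], d[, m[2]], d[, m[3]]))
    if (cost < best_cost - 1e-12) {
      best_cost <- cost
      best <- m
    }
  }
  list(medoids = best, cost = best_cost)
}

# Deterministic PAM: greedy build then best-improvement swap phase.
pam_medoids <- function(d, k = 3L) {
  n <- nrow(d)
  medoids <- which.min(colSums(d))
  while (length(medoids) < k) {
    cur <- apply(d[, medoids, drop = FALSE], 1L, min)
    gain <- vapply(seq_len(n), function(j) {
      if (j %in% medoids) return(-Inf)
      sum(pmax(cur - d[, j], 0))
    }, numeric(1))
    medoids <- c(medoids, which.max(gain))
  }
  cost <- sum(pmin(d[, medoids[1]], d[, medoids[2]], d[, medoids[3]]))
  repeat {
    best_delta <- 0
    best_swap <- NULL
    for (mi in seq_along(medoids)) {
      for (h in seq_len(n)) {
        if (h %in% medoids) next
        cand <- medoids
        cand[mi] <- h
        new_cost <- sum(pmin(d[, cand[1]], d[, cand[2]], d[, cand[3]]))
        delta <- new_cost - cost
        if (delta < best_delta - 1e-12) {
          best_delta <- delta
          best_swap <- cand
        }
      }
    }
    if (is.null(best_swap)) break
    medoids <- best_swap
    cost <- cost + best_delta
  }
  list(medoids = sort(medoids), cost = cost)
}

nearest_medoid <- function(d, medoids) {
  dm <- d[, medoids, drop = FALSE]
  max.col(-dm, ties.method = "first")
}

# Relabel group ids 1..k by ascending mean RR.
order_groups_by_mean <- function(grp, rr) {
  means <- tapply(rr, grp, mean)
  ranks <- rank(means, ties.method = "first")
  unname(ranks[as.character(grp)])
}

# Within-group spread objective: pooled within-group sum of squares of the
# raw RR values. Size-weighting matters: an unweighted sum of per-group sds
# can be *lowered* by diluting a contaminated group with far-away points,
# which collapses the partition; the pooled form cannot.
group_spread <- function(grp, rr) {
  sum(vapply(split(rr, grp), function(x) sum((x - mean(x))^2), numeric(1)))
}

# Greedy fine-tuning restricted to feature-space-plausible moves: an interval
# may only switch to the group of its second-nearest medoid, and only when
# the summed within-group RR spread strictly drops. Groups are never emptied
# below 2 members.
fine_tune_groups <- function(grp, rr, d, medoids, max_passes = 1L) {
  if (anyNA(medoids)) return(grp)
  dm <- d[, medoids, drop = FALSE]
  ord <- t(apply(dm, 1L, order))
  # medoid column -> group label: each medoid carries its own group's label
  lab <- grp[medoids]

  cur <- group_spread(grp, rr)
  for (pass in seq_len(max_passes)) {
    moved <- FALSE
    for (i in seq_along(rr)) {
      target <- lab[ord[i, 2L]]
      if (is.na(target) || target == grp[i]) next
      if (sum(grp == grp[i]) <= 2L) next
      trial <- grp
      trial[i] <- target
      val <- group_spread(trial, rr)
      if (val < cur - 1e-12) {
        grp <- trial
        cur <- val
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  grp
}

new_paf_cluster <- function(rr, grp, medoid_index, cost, degenerate) {
  means <- tapply(rr, grp, mean)
  sizes <- tabulate(grp, nbins = max(grp))
  structure(
    list(assignment = as.integer(grp),
         medoid_index = medoid_index,
         group_means = as.numeric(means),
         group_sizes = as.integer(sizes[sort(unique(grp))]),
         n_groups = length(unique(grp)),
         cost = cost,
         degenerate = degenerate,
         rr = rr),
    class = "paf_cluster")
}

#' @export
print.paf_cluster <- function(x, ...) {
  cat(sprintf("<paf_cluster> %d RRs, %d group(s)%s\n", length(x$rr),
              x$n_groups, if (x$degenerate) " [degenerate]" else ""))
  cat("  group mean RR (s):", paste(sprintf("%.3f", x$group_means),
                                    collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn cluster_rr Per-interval tibble: `index`, `rr_s`, `group`.
#' @param x A `paf_cluster`.
#' @param ... Unused.
#' @method tidy paf_cluster
#' @export
tidy.paf_cluster <- function(x, ...) {
  tibble(index = seq_along(x$rr), rr_s = x$rr, group = x$assignment)
}

#' @describeIn cluster_rr One-row summary: group means/sizes, cost, flags.
#' @method glance paf_cluster
#' @export
glance.paf_cluster <- function(x, ...) {
  tibble(n = length(x$rr), n_groups = x$n_groups, cost = x$cost,
         degenerate = x$degenerate,
         mean_rr_low = x$group_means[1],
         mean_rr_high = x$group_means[x$n_groups])
}
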