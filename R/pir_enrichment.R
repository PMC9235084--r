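## Feature enrichment at promoter-interacting regions (PIRs): are genomic
## features over-represented at the other-end fragments of high-confidence
## promoter-capture interactions, relative to random fragment sets matched
## on distance to the nearest bait? The null is fragment-level and
## distance-matched because interaction other-ends are concentrated near
## promoters; an unmatched null would confound feature enrichment with
## promoter proximity.

#' Keep high-confidence interaction calls
#'
#' Retains calls with `score >= threshold` (inclusive) and deduplicates
#' identical bait/other-end pairs, keeping the maximum score.
#'
#' @param calls interaction data.frame (`bait_id,otherend_id,score`).
#' @param threshold confidence threshold (default 5).
#' @return filtered interaction data.frame.
#' @export
filter_significant <- function(calls, threshold = 5) {
  keep <- calls[calls$score >= threshold, , drop = FALSE]
  keep <- keep[order(-keep$score), , drop = FALSE]
  keep <- keep[!duplicated(keep[, c("bait_id", "otherend_id")]), , drop = FALSE]
  keep <- keep[order(keep$bait_id, keep$otherend_id), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' Distance-matched resampling enrichment of a feature at PIRs
#'
#' The tested set is the distinct other-end fragments of calls whose
#' midpoint lies in cis within `max_dist` of their bait midpoint;
#' `observed` counts those overlapping (>= 1 bp) at least one feature
#' interval. The null draws `n_rand` random sets of non-bait, non-tested
#' fragments with the same size and the same composition of
#' distance-to-nearest-bait across `n_dist_bins` log-spaced distance bins
#' (sampling without replacement within an iteration), and records each
#' set's overlap count. The expected overlap is the null mean, the 95%
#' interval its 2.5/97.5 percentiles, `fold = observed / expected` (with a
#' log-normal 95% CI for the fold itself in `fold_ci_low/fold_ci_high`).
#' Two p-values are reported side by side: a two-sided empirical tail
#' probability with +1 smoothing (granularity `1/(n_rand+1)`), and a
#' two-sided normal-approximation p using the analytic variance of the
#' observed count under the generative null (useful for tails smaller than
#' the resampling resolution).
#'
#' @param calls interaction data.frame (use [filter_significant()] first).
#' @param fragments fragment map (`chrom,start,end,fragment_id,is_bait`).
#' @param feature feature interval data.frame (`chrom,start,end`).
#' @param max_dist maximum bait distance in bp (default 1 Mb).
#' @param n_rand number of random fragment sets (default 100).
#' @param n_dist_bins number of log-spaced distance bins (default 20).
#' @param seed RNG seed for the resampling.
#' @param feature_name label carried into the result.
#' @return a one-row data.frame of class `feature_enrichment`:
#'   `feature_name, n_tested_fragments, observed, expected_mean, ci_low,
#'   ci_high, fold, fold_ci_low, fold_ci_high, p_value, p_value_z, n_rand, seed, flag`.
#' @export
feature_enrichment <- function(calls, fragments, feature, max_dist = 1e6,
                               n_rand = 100, n_dist_bins = 20, seed = 1,
                               feature_name = "feature") {
  frag_row <- match(calls$bait_id, fragments$fragment_id)
  oe_row <- match(calls$otherend_id, fragments$fragment_id)
  if (anyNA(frag_row) || anyNA(oe_row)) stopf("calls reference fragments missing from the map")
  mid <- (fragments$start + fragments$end) / 2
  cis <- fragments$chrom[frag_row] == fragments$chrom[oe_row]
  d <- abs(mid[frag_row] - mid[oe_row])
  use <- cis & d <= max_dist
  # tested set: distinct non-bait other-end fragments (bait-to-bait calls
  # are not PIRs and have no analog in the non-bait background pool)
  tested_rows <- sort(unique(oe_row[use]))
  tested_rows <- tested_rows[!fragments$is_bait[tested_rows]]
  n_tested <- length(tested_rows)
  if (n_tested == 0) stopf("no tested fragments (no cis calls within max_dist)")

  result <- function(observed, expected_mean, ci, null, var_null_gen = 0,
                     var_exp_gen = 0, flag = "") {
    sdn <- if (length(null) > 1) sd(null) else 0
    if (length(null)) {
      p_up <- (sum(null >= observed) + 1) / (length(null) + 1)
      p_dn <- (sum(null <= observed) + 1) / (length(null) + 1)
      p_emp <- min(1, 2 * min(p_up, p_dn))
    } else {
      p_emp <- 1
    }
    # normal-approximation p against the generative null: the resampling
    # null conditions on the realized feature map and the fixed pool, so
    # its spread understates the variance of the observed count (finite
    # pool, binomial feature assignment); use the analytic variance
    var_z <- var_null_gen + var_exp_gen
    p_z <- if (var_z > 0) {
      2 * pnorm(-abs((observed - expected_mean) / sqrt(var_z)))
    } else {
      if (observed == expected_mean) 1 else 0
    }
    fold <- if (expected_mean > 0) observed / expected_mean else if (observed == 0) 0 else Inf
    # 95% CI of the fold estimate: binomial noise in the observed count,
    # finite-pool noise in the background rate, and Monte-Carlo noise of
    # the null mean. The CI is log-normal (delta method on the log scale),
    # the standard construction for a positive ratio estimate.
    if (expected_mean > 0 && observed > 0) {
      se_obs2 <- observed * max(0, 1 - observed / n_tested)
      se_exp2 <- var_exp_gen + if (length(null) > 1) sdn^2 / length(null) else 0
      se_rel <- sqrt(se_obs2 / observed^2 + se_exp2 / expected_mean^2)
      fold_ci <- fold * exp(c(-1.96, 1.96) * se_rel)
    } else {
      fold_ci <- c(NA_real_, NA_real_)
    }
    out <- data.frame(feature_name = feature_name, n_tested_fragments = n_tested,
                      observed = observed, expected_mean = expected_mean,
                      ci_low = ci[1], ci_high = ci[2], fold = fold,
                      fold_ci_low = fold_ci[1], fold_ci_high = fold_ci[2],
                      p_value = p_emp, p_value_z = p_z, n_rand = length(null),
                      seed = seed, flag = flag, stringsAsFactors = FALSE)
    class(out) <- c("feature_enrichment", "data.frame")
    out
  }

  if (nrow(feature) == 0) {
    return(result(0, 0, c(0, 0), numeric(0), flag = "empty_feature"))
  }
  has_feature <- overlaps_any(fragments, feature)
  observed <- sum(has_feature[tested_rows])

  # eligible background: non-bait, non-tested fragments; the matching
  # covariate, for tested and background fragments alike, is distance to
  # the nearest bait on the same chromosome (promoters are the baits, so
  # this is "distance from gene promoters")
  pool <- setdiff(which(!fragments$is_bait), tested_rows)
  bait_mid <- split(mid[fragments$is_bait], fragments$chrom[fragments$is_bait])
  nearest_bait_dist <- function(rows) {
    out <- rep(Inf, length(rows))
    for (ch in unique(fragments$chrom[rows])) {
      bm <- bait_mid[[ch]]
      if (is.null(bm) || !length(bm)) next
      sel <- fragments$chrom[rows] == ch
      out[sel] <- vapply(mid[rows[sel]], function(m) min(abs(bm - m)), 0)
    }
    out
  }
  td <- nearest_bait_dist(tested_rows)
  pd <- nearest_bait_dist(pool)

  # log-spaced distance bins from 0 to the largest tested distance, offset
  # by a 5 kb soft scale so the finest bins are no narrower than a typical
  # restriction fragment (matching below fragment scale is meaningless)
  hi <- max(td)
  soft <- 5000
  edges <- exp(seq(log(soft), log(hi + soft), length.out = n_dist_bins + 1)) - soft
  edges[1] <- 0
  bin_of <- function(x) {
    b <- findInterval(x, edges, rightmost.closed = TRUE)
    b[x > hi] <- NA_integer_
    pmin(pmax(b, 1L), n_dist_bins)
  }
  tb <- bin_of(td)
  pb <- bin_of(pd)
  m_b <- tabulate(tb, nbins = n_dist_bins)
  pool_by_bin <- split(pool, factor(pb, levels = seq_len(n_dist_bins)))
  # merge bins whose background pool cannot supply the draw into their
  # neighbor (the distance composition is preserved at the achievable
  # resolution); error only when matching is infeasible outright
  groups <- lapply(seq_len(n_dist_bins), identity)
  repeat {
    need <- vapply(groups, function(g) sum(m_b[g]), 0L)
    have <- vapply(groups, function(g) sum(lengths(pool_by_bin[g])), 0L)
    bad <- which(need > have)
    if (!length(bad)) break
    if (length(groups) == 1) {
      stopf("too few eligible background fragments in distance bin %d-%d (%.0f-%.0f bp): need %d, have %d",
            min(groups[[1]]), max(groups[[1]]), edges[min(groups[[1]])],
            edges[max(groups[[1]]) + 1], need[1], have[1])
    }
    g <- bad[1]
    nb <- if (g < length(groups)) g + 1 else g - 1
    groups[[min(g, nb)]] <- c(groups[[min(g, nb)]], groups[[max(g, nb)]])
    groups[[max(g, nb)]] <- NULL
  }
  draw_groups <- Filter(function(g) sum(m_b[g]) > 0, groups)
  group_pool <- lapply(draw_groups, function(g) unlist(pool_by_bin[g], use.names = FALSE))
  group_need <- vapply(draw_groups, function(g) sum(m_b[g]), 0L)
  null <- with_seed(seed, {
    vapply(seq_len(n_rand), function(r) {
      tot <- 0L
      for (k in seq_along(draw_groups)) {
        pick <- group_pool[[k]][sample.int(length(group_pool[[k]]), group_need[k])]
        tot <- tot + sum(has_feature[pick])
      }
      tot
    }, 0L)
  })
  ci <- quantile(null, c(0.025, 0.975), names = FALSE)
  r_k <- vapply(group_pool, function(g) mean(has_feature[g]), 0)
  n_k <- lengths(group_pool)
  var_null_gen <- sum(group_need * r_k * (1 - r_k))
  var_exp_gen <- sum(group_need^2 * r_k * (1 - r_k) / n_k)
  result(observed, mean(null), ci, null, var_null_gen, var_exp_gen)
}
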