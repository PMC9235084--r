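## ChIP-MS binding-partner selection and downstream GO over-representation.
## The partner rule: a protein is a binding partner in an experiment group
## iff it is present in both WT immunoprecipitation replicates
## (wt1 != 0 and wt2 != 0) and its replicate-average WT/DKO abundance ratio
## is at least the threshold (default 10). A protein absent from both DKO
## replicates has an infinite ratio and passes any finite threshold.

#' Apply the WT/DKO binding-partner filter
#'
#' For each abundance record computes `wt_ave = (wt1 + wt2) / 2`,
#' `dko_ave = (dko1 + dko2) / 2` and their ratio (infinite when
#' `dko_ave = 0` with positive WT), and calls a partner when both WT
#' replicates are nonzero and the ratio is at or above `threshold`
#' (inclusive). The call is invariant to rescaling all abundances by a
#' positive constant. With `pseudocount > 0` the ratio becomes
#' `wt_ave / (dko_ave + pseudocount)` (off by default; the infinite-ratio
#' convention matches knockout-absent partners without pseudocounts).
#'
#' @param records abundance data.frame
#'   (`protein_id,group,wt1,wt2,dko1,dko2`), one row per protein per group.
#' @param threshold minimum WT/DKO average ratio (default 10).
#' @param pseudocount optional additive constant on the DKO average.
#' @return data.frame `protein_id, group, wt_ave, dko_ave, ratio,
#'   is_partner, threshold`.
#' @export
select_partners <- function(records, threshold = 10, pseudocount = 0) {
  if (nrow(records) == 0) stopf("no abundance records")
  ab <- as.matrix(records[, c("wt1", "wt2", "dko1", "dko2")])
  if (any(!is.finite(ab)) || any(ab < 0)) stopf("abundances must be finite and non-negative")
  if (anyDuplicated(records[, c("protein_id", "group")])) {
    stopf("more than one record per (protein, group)")
  }
  wt_ave <- (records$wt1 + records$wt2) / 2
  dko_ave <- (records$dko1 + records$dko2) / 2
  denom <- dko_ave + pseudocount
  ratio <- ifelse(denom > 0, wt_ave / denom, ifelse(wt_ave > 0, Inf, NA_real_))
  is_partner <- records$wt1 != 0 & records$wt2 != 0 &
    !is.na(ratio) & ratio >= threshold
  data.frame(protein_id = records$protein_id, group = records$group,
             wt_ave = wt_ave, dko_ave = dko_ave, ratio = ratio,
             is_partner = is_partner, threshold = threshold,
             stringsAsFactors = FALSE)
}

#' Partner counts across a sweep of ratio thresholds
#'
#' Applies the partner filter at each threshold and tallies partners two
#' ways: as distinct (protein, group) pairs pooled across groups, and as
#' distinct proteins. By default the 500 threshold is strict (`>`) while
#' the others are inclusive (`>=`), matching the convention of reporting a
#' "> 500-fold" cut alongside ">= 10" and ">= 50" cuts. Counts are
#' monotone non-increasing in the threshold.
#'
#' @param records abundance data.frame.
#' @param thresholds positive ascending thresholds (default 10, 50, 500).
#' @param strict logical per threshold: use `>` instead of `>=`.
#' @return data.frame `threshold, strict, n_protein_group, n_proteins`.
#' @export
threshold_sweep <- function(records, thresholds = c(10, 50, 500),
                            strict = thresholds == 500) {
  if (nrow(records) == 0) stopf("no abundance records")
  if (any(thresholds <= 0) || is.unsorted(thresholds, strictly = TRUE)) {
    stopf("thresholds must be positive and ascending")
  }
  stopifnot(length(strict) == length(thresholds))
  base <- select_partners(records, threshold = 0)
  eligible <- records$wt1 != 0 & records$wt2 != 0 & !is.na(base$ratio)
  out <- do.call(rbind, lapply(seq_along(thresholds), function(k) {
    pass <- eligible & if (strict[k]) base$ratio > thresholds[k] else base$ratio >= thresholds[k]
    data.frame(threshold = thresholds[k], strict = strict[k],
               n_protein_group = sum(pass),
               n_proteins = length(unique(base$protein_id[pass])))
  }))
  if (is.unsorted(rev(out$n_protein_group)) || is.unsorted(rev(out$n_proteins))) {
    stopf("internal error: partner counts not monotone in threshold") # nocov
  }
  out
}

#' GO over-representation analysis (one-sided Fisher / hypergeometric)
#'
#' For each annotation term (members intersected with the universe; empty
#' intersections skipped) the one-sided Fisher exact p-value for
#' over-representation is the hypergeometric upper tail of the sample/term
#' overlap. Benjamini-Hochberg FDR is applied across all tested terms and
#' results are sorted by descending `-log10(q)`.
#'
#' @param sample protein id set (must be a subset of `universe`).
#' @param universe background protein id set.
#' @param annotation named list as from [read_gmt()] or
#'   [simulate_go_annotation()].
#' @param alpha significance level used for the `significant` flag
#'   (default 0.05).
#' @return data.frame `term_id, term_name, sample_count, background_count,
#'   expected, enrichment_score, p_value, q_value, neg_log10_q,
#'   significant`.
#' @export
ora <- function(sample, universe, annotation, alpha = 0.05) {
  sample <- unique(sample); universe <- unique(universe)
  if (!all(sample %in% universe)) stopf("sample contains proteins outside the universe")
  N <- length(universe); n <- length(sample)
  rows <- lapply(names(annotation), function(id) {
    members <- intersect(annotation[[id]]$members, universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(sample, members))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    expected <- n * K / N
    data.frame(term_id = id, term_name = annotation[[id]]$name,
               sample_count = k, background_count = K, expected = expected,
               enrichment_score = k / expected, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no annotation terms overlap the universe")
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$neg_log10_q <- -log10(pmax(out$q_value, 1e-300))
  out$significant <- out$q_value < alpha
  out <- out[order(-out$neg_log10_q, out$p_value, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Consensus GO categories across experiment groups
#'
#' A term is a consensus category iff its FDR q-value is below `alpha` in
#' every required group (both immunoprecipitation targets in both cell
#' types, in the four-experiment design). Also reported: "common" terms
#' significant in at least two groups, "unique" terms significant in
#' exactly one, and the consensus ranking by the combined `-log10(q)`
#' summed over groups.
#'
#' @param results_by_group named list of [ora()] result data.frames.
#' @param alpha significance level (default 0.05).
#' @param required_groups group names that must all be present.
#' @return `list(consensus, n_consensus, n_common, n_unique,
#'   unique_by_group, n_significant_by_group)`.
#' @export
consensus_categories <- function(results_by_group, alpha = 0.05,
                                 required_groups = c("ES_N1", "ES_N2", "MEF_N1", "MEF_N2")) {
  missing <- setdiff(required_groups, names(results_by_group))
  if (length(missing)) stopf("missing group(s): %s", paste(missing, collapse = ", "))
  res <- results_by_group[required_groups]
  sig <- lapply(res, function(r) r$term_id[r$q_value < alpha])
  all_terms <- unique(unlist(lapply(res, `[[`, "term_id")))
  n_sig_in <- vapply(all_terms, function(t) sum(vapply(sig, function(s) t %in% s, TRUE)), 0L)
  consensus_ids <- all_terms[n_sig_in == length(required_groups)]
  combined <- vapply(consensus_ids, function(t) {
    sum(vapply(res, function(r) r$neg_log10_q[match(t, r$term_id)], 0))
  }, 0)
  names_of <- function(t) res[[1]]$term_name[match(t, res[[1]]$term_id)]
  consensus <- data.frame(term_id = consensus_ids,
                          term_name = names_of(consensus_ids),
                          combined_neg_log10_q = combined,
                          stringsAsFactors = FALSE)
  consensus <- consensus[order(-consensus$combined_neg_log10_q, consensus$term_id), ]
  rownames(consensus) <- NULL
  unique_by_group <- vapply(required_groups, function(g) {
    sum(vapply(sig[[g]], function(t) n_sig_in[[t]] == 1L, TRUE))
  }, 0L)
  list(consensus = consensus,
       n_consensus = nrow(consensus),
       n_common = sum(n_sig_in >= 2),
       n_unique = sum(n_sig_in == 1),
       unique_by_group = unique_by_group,
       n_significant_by_group = vapply(sig, length, 0L))
}
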