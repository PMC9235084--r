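## Peak/compartment co-localization and boundary metaplots: how much of a
## protein's binding sits in the active (A) compartment, and how its signal
## behaves across B-to-A transitions.

#' Fraction of peaks in the A compartment
#'
#' Each peak is assigned to the compartment of the bin containing its
#' midpoint (or, with `assign = "max_overlap"`, the labeled bin it overlaps
#' most, ties to the lower bin). Peaks landing in masked (NA) bins, or
#' outside the bin table, are excluded from both numerator and denominator
#' and reported separately.
#'
#' @param peaks peak data.frame (`chrom,start,end`).
#' @param profile a labeled `compartment_profile`.
#' @param assign `"midpoint"` (default) or `"max_overlap"`.
#' @return `list(n_peaks, n_in_A, fraction_A, n_excluded)` where `n_peaks`
#'   counts only assessable peaks.
#' @export
peak_compartment_fraction <- function(peaks, profile, assign = c("midpoint", "max_overlap")) {
  assign <- match.arg(assign)
  if (nrow(peaks) == 0) stopf("no peaks")
  bins <- profile[, c("chrom", "start", "end", "index")]
  if (assign == "midpoint") {
    mid <- floor((peaks$start + peaks$end) / 2)
    q <- GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(mid + 1, mid + 1))
    hit <- GenomicRanges::findOverlaps(q, gr_from_df(bins), select = "first")
  } else {
    hits <- GenomicRanges::findOverlaps(gr_from_df(peaks), gr_from_df(bins))
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    w <- IRanges::width(IRanges::pintersect(IRanges::ranges(gr_from_df(peaks))[qi],
                                            IRanges::ranges(gr_from_df(bins))[si]))
    hit <- rep(NA_integer_, nrow(peaks))
    for (p in unique(qi)) {
      sel <- qi == p
      hit[p] <- si[sel][which.max(w[sel])]
    }
  }
  lab <- rep(NA_character_, nrow(peaks))
  lab[!is.na(hit)] <- profile$label[hit[!is.na(hit)]]
  assessed <- !is.na(lab)
  n_in_a <- sum(lab[assessed] == "A")
  list(n_peaks = sum(assessed),
       n_in_A = n_in_a,
       fraction_A = n_in_a / sum(assessed),
       n_excluded = sum(!assessed))
}

#' Average a signal track across compartment boundaries
#'
#' For each boundary the signal is sampled at offsets `-window .. +window`
#' in steps of `step`, with the B side at negative offsets and the A side
#' at positive offsets (boundaries are B-to-A positions). Offsets falling
#' outside the chromosome (taken as the extent of the signal track)
#' are dropped for that boundary; offsets inside the chromosome but not
#' covered by any track interval contribute 0 and are reflected in the
#' `coverage_fraction` column.
#'
#' @param signal signal track data.frame (`chrom,start,end,value`).
#' @param boundaries data.frame `chrom,pos` (e.g. from
#'   [find_boundaries()]).
#' @param window half-window in bp (default 200 kb).
#' @param step sampling step in bp (typically the bin size).
#' @return data.frame `offset, mean_signal, n_boundaries,
#'   coverage_fraction`.
#' @export
boundary_metaplot <- function(signal, boundaries, window = 200000, step = 25000) {
  if (nrow(boundaries) == 0) stopf("no boundaries")
  offsets <- seq(-window, window, by = step)
  extent <- tapply(signal$end, signal$chrom, max)
  nb <- nrow(boundaries)
  pos <- rep(boundaries$pos, each = length(offsets)) + rep(offsets, nb)
  chrom <- rep(boundaries$chrom, each = length(offsets))
  inside <- pos >= 0 & pos < extent[chrom]
  tv <- track_values_at(signal, chrom, pos)
  val <- matrix(tv$value, nrow = length(offsets))
  cov <- matrix(tv$covered, nrow = length(offsets))
  ok <- matrix(inside, nrow = length(offsets))
  mean_signal <- vapply(seq_along(offsets), function(k) {
    if (!any(ok[k, ])) return(NA_real_)
    mean(val[k, ok[k, ]])
  }, 0)
  data.frame(offset = offsets,
             mean_signal = mean_signal,
             n_boundaries = rowSums(ok),
             coverage_fraction = vapply(seq_along(offsets), function(k) {
               if (!any(ok[k, ])) return(NA_real_)
               mean(cov[k, ok[k, ]])
             }, 0))
}
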