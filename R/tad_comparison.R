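## Insulation-score TAD boundary calling and condition-vs-condition TAD
## invariance. TADs show elevated within-domain and depleted cross-domain
## contact frequency; the insulation score at a bin measures contact flow
## across it, so boundaries appear as local minima. Hierarchy/nesting is
## not modeled: the comparisons downstream rest on counts, sizes and
## boundary stability only.

#' Per-bin insulation profile of a contact matrix
#'
#' For each bin `i`, the mean count in the `w x w` square spanning the `w`
#' bins upstream by the `w` bins downstream of `i` is computed and the
#' score is its log2 ratio to the chromosome-wide mean of that statistic
#' (so a uniform matrix scores 0 everywhere and the score is invariant to
#' global count scaling). Bins within `w` bins of a chromosome end, bins
#' whose square is entirely masked (only zero-marginal bins), and bins with
#' an all-zero square get NA.
#'
#' @param matrix a `contact_matrix`.
#' @param window insulation window in bp (default 500 kb); must span at
#'   least 2 bins and fit inside each chromosome.
#' @return data.frame `chrom,start,end,index,insulation`.
#' @export
insulation_profile <- function(matrix, window = 5e5) {
  stopifnot(inherits(matrix, "contact_matrix"))
  bins <- matrix$bins
  score <- rep(NA_real_, nrow(bins))
  for (ch in unique(bins$chrom)) {
    idx <- bins$index[bins$chrom == ch]
    M <- cm_dense(matrix, ch)
    n <- nrow(M)
    bw <- median(bins$end[bins$chrom == ch] - bins$start[bins$chrom == ch])
    w <- round(window / bw)
    if (w < 2) stopf("window must span at least 2 bins")
    if (2 * w + 1 > n) stopf("window larger than chromosome %s", ch)
    usable <- rowSums(M) > 0
    raw <- rep(NA_real_, n)
    for (i in (w + 1):(n - w)) {
      rows <- (i - w):(i - 1)
      cols <- (i + 1):(i + w)
      ok <- outer(usable[rows], usable[cols], "&")
      if (!any(ok)) next
      raw[i] <- mean(M[rows, cols][ok])
    }
    mu <- mean(raw, na.rm = TRUE)
    sc <- ifelse(!is.na(raw) & raw > 0 & mu > 0, log2(raw / mu), NA_real_)
    score[idx] <- sc
  }
  data.frame(bins, insulation = score)
}

#' Call TAD boundaries and domains from an insulation profile
#'
#' Boundaries are local insulation minima whose depth below the nearest
#' flanking maxima (the defined-region endpoints count as flanks) exceeds
#' `min_drop`. Domains span the intervals between successive boundaries
#' (and between a chromosome's defined ends and its outermost boundaries),
#' filtered to `[min_size, max_size]`.
#'
#' @param insulation data.frame from [insulation_profile()].
#' @param min_drop minimum boundary depth in log2 units (default 0.1).
#' @param min_size,max_size domain size filter in bp.
#' @return a `tad_set`: `list(boundaries, tads, insulation)`.
#' @export
call_tads <- function(insulation, min_drop = 0.1, min_size = 75000, max_size = 5e6) {
  bound <- list(); doms <- list()
  for (ch in unique(insulation$chrom)) {
    p <- insulation[insulation$chrom == ch, ]
    def <- which(!is.na(p$insulation))
    if (length(def) < 3) next
    x <- p$insulation[def]
    len <- length(x)
    is_min <- c(FALSE, x[2:(len - 1)] < x[1:(len - 2)] & x[2:(len - 1)] <= x[3:len], FALSE)
    mins <- which(is_min)
    accepted <- integer()
    for (t in mins) {
      lo <- max(c(1, mins[mins < t] + 1))
      hi <- min(c(len, mins[mins > t] - 1))
      left_max <- max(x[lo:(t - 1)])
      right_max <- max(x[(t + 1):hi])
      if (min(left_max, right_max) - x[t] > min_drop) accepted <- c(accepted, t)
    }
    bidx <- def[accepted]
    if (!length(bidx)) next  # no boundaries: no domains on this chromosome
    bound[[length(bound) + 1]] <- data.frame(
      chrom = ch, index = p$index[bidx], pos = p$start[bidx])
    delim <- c(def[1], bidx, def[len])
    if (length(delim) >= 2) {
      for (k in seq_len(length(delim) - 1)) {
        sb <- delim[k]
        eb <- if (k == length(delim) - 1) delim[k + 1] else delim[k + 1] - 1
        if (eb < sb) next
        size <- p$end[eb] - p$start[sb]
        if (size < min_size || size > max_size) next
        doms[[length(doms) + 1]] <- data.frame(
          chrom = ch, start_bin = p$index[sb], end_bin = p$index[eb],
          start = p$start[sb], end = p$end[eb], size = size)
      }
    }
  }
  empty_b <- data.frame(chrom = character(), index = integer(), pos = numeric())
  empty_t <- data.frame(chrom = character(), start_bin = integer(), end_bin = integer(),
                        start = numeric(), end = numeric(), size = numeric())
  out <- list(boundaries = if (length(bound)) do.call(rbind, bound) else empty_b,
              tads = if (length(doms)) do.call(rbind, doms) else empty_t,
              insulation = insulation)
  class(out) <- "tad_set"
  out
}

#' Compare two TAD sets on the same bin table
#'
#' Boundaries are matched greedily by nearest bin distance, each boundary
#' used at most once, with a match allowed within `tolerance` bins. The
#' Jaccard index is `matched / (n_a + n_b - matched)` (defined as 1 when
#' both sets are empty). Domain-size quantiles are reported at
#' 10/25/50/75/90%.
#'
#' @param a,b `tad_set` objects.
#' @param tolerance match tolerance in bins (default 1).
#' @return `list(n_tads_a, n_tads_b, size_quantiles_a, size_quantiles_b,
#'   boundary_jaccard)`.
#' @export
compare_tads <- function(a, b, tolerance = 1) {
  stopifnot(inherits(a, "tad_set"), inherits(b, "tad_set"))
  matched <- 0
  chroms <- union(a$boundaries$chrom, b$boundaries$chrom)
  for (ch in chroms) {
    ai <- a$boundaries$index[a$boundaries$chrom == ch]
    bi <- b$boundaries$index[b$boundaries$chrom == ch]
    if (!length(ai) || !length(bi)) next
    pairs <- expand.grid(x = seq_along(ai), y = seq_along(bi))
    pairs$d <- abs(ai[pairs$x] - bi[pairs$y])
    pairs <- pairs[pairs$d <= tolerance, ]
    pairs <- pairs[order(pairs$d), ]
    used_a <- logical(length(ai)); used_b <- logical(length(bi))
    for (r in seq_len(nrow(pairs))) {
      if (!used_a[pairs$x[r]] && !used_b[pairs$y[r]]) {
        used_a[pairs$x[r]] <- TRUE
        used_b[pairs$y[r]] <- TRUE
        matched <- matched + 1
      }
    }
  }
  na <- nrow(a$boundaries); nb <- nrow(b$boundaries)
  jac <- if (na + nb == 0) 1 else matched / (na + nb - matched)
  qs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  size_q <- function(t) {
    if (nrow(t) == 0) return(setNames(rep(NA_real_, length(qs)), paste0(qs * 100, "%")))
    quantile(t$size, qs, names = TRUE)
  }
  list(n_tads_a = nrow(a$tads),
       n_tads_b = nrow(b$tads),
       size_quantiles_a = size_q(a$tads),
       size_quantiles_b = size_q(b$tads),
       boundary_jaccard = jac)
}
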