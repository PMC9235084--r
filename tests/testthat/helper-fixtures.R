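# Shared fixtures and independent oracles. The oracles deliberately use
# plain loops and textbook formulas so they share no code path with the
# implementation they check.

# a contact_matrix from a dense symmetric matrix on one synthetic chromosome
dense_to_cm <- function(M, bin_size = 25000, chrom = "chrT") {
  n <- nrow(M)
  bins <- make_bins(setNames(n * bin_size, chrom), bin_size)
  ut <- which(upper.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
  contact_matrix(bins, data.frame(i = ut[, 1], j = ut[, 2], count = M[ut]))
}

# constant-value signal track covering a set of bins
flat_track <- function(bins, value = 1) {
  data.frame(chrom = bins$chrom, start = bins$start, end = bins$end, value = value)
}

# small config for fast end-to-end pieces
small_cfg <- function(seed = 1, ...) {
  sim_config(chrom_sizes = c(chrSynA = 6e6, chrSynB = 5e6), n_fragments = 1200,
             n_baits = 60, calls_per_bait = 6, n_proteins = 300,
             n_go_terms = 20, seed = seed, ...)
}

# config used by the PIR enrichment recovery/calibration checks
pir_cfg <- function(seed, phi) {
  sim_config(seed = seed, chrom_sizes = c(chrSyn = 8e6), n_fragments = 2000,
             n_baits = 80, calls_per_bait = 6, feature_fold = phi)
}

# ---- compartment score oracle: dense, loop-based, full eigendecomposition
oracle_cscores <- function(M, ref_vals) {
  n <- nrow(M)
  marg <- vapply(seq_len(n), function(i) sum(M[i, ]), 0)
  usable <- marg > 0
  exp_d <- rep(NA_real_, n)
  for (dd in 0:(n - 1)) {
    vals <- c()
    for (i in seq_len(n - dd)) {
      j <- i + dd
      if (usable[i] && usable[j]) vals <- c(vals, M[i, j])
    }
    if (length(vals)) exp_d[dd + 1] <- mean(vals)
  }
  OE <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    e <- exp_d[abs(i - j) + 1]
    if (!is.na(e) && e > 0) OE[i, j] <- M[i, j] / e
  }
  keep <- usable
  for (i in which(usable)) {
    if (stats::sd(OE[usable, i]) == 0) keep[i] <- FALSE
  }
  C <- stats::cor(OE[keep, keep])
  eg <- eigen(C)
  v <- Re(eg$vectors[, which.max(abs(Re(eg$values)))])
  v <- v / max(abs(v))
  if (stats::sd(ref_vals[keep]) > 0 && stats::cor(v, ref_vals[keep]) < 0) v <- -v
  out <- rep(NA_real_, n)
  out[keep] <- v
  out
}

# ---- SCC oracle: per-diagonal textbook Pearson, direct neighborhood smooth
oracle_smooth <- function(M, h) {
  n <- nrow(M)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    vals <- c()
    for (a in max(1, i - h):min(n, i + h)) {
      for (b in max(1, j - h):min(n, j + h)) vals <- c(vals, M[a, b])
    }
    S[i, j] <- mean(vals)
  }
  S
}

oracle_scc <- function(A, B, h, max_k) {
  A <- oracle_smooth(A, h)
  B <- oracle_smooth(B, h)
  n <- nrow(A)
  wsum <- 0; wrsum <- 0
  for (k in 0:min(max_k, n - 1)) {
    av <- c(); bv <- c()
    for (i in seq_len(n - k)) {
      av <- c(av, A[i, i + k]); bv <- c(bv, B[i, i + k])
    }
    n_k <- length(av)
    if (n_k < 3) next
    ma <- sum(av) / n_k; mb <- sum(bv) / n_k
    sa <- sqrt(sum((av - ma)^2) / (n_k - 1))
    sb <- sqrt(sum((bv - mb)^2) / (n_k - 1))
    if (sa == 0 || sb == 0) next
    r <- sum((av - ma) * (bv - mb)) / ((n_k - 1) * sa * sb)
    w <- n_k * sa * sb
    wsum <- wsum + w; wrsum <- wrsum + w * r
  }
  wrsum / wsum
}

# ---- hypergeometric upper-tail closed form
oracle_hyper_p <- function(k, K, N, n) {
  tot <- 0
  for (x in k:min(K, n)) tot <- tot + choose(K, x) * choose(N - K, n - x)
  tot / choose(N, n)
}

# ---- exhaustive-null toy for feature enrichment ------------------------
# 8 fragments of 1 kb on one chromosome; F2 is the only bait; calls target
# F1, F4, F8 (tested, nearest-bait distances 1, 2 and 6 kb); the background
# pool is F3, F5, F6, F7 (distances 1-5 kb, all within the tested range).
enrichment_toy <- function() {
  fragments <- data.frame(chrom = "chrT",
                          start = 0:7 * 1000, end = 1:8 * 1000,
                          fragment_id = paste0("F", 1:8),
                          is_bait = c(FALSE, TRUE, rep(FALSE, 6)))
  calls <- data.frame(bait_id = "F2", otherend_id = c("F1", "F4", "F8"),
                      score = c(6, 7, 8))
  # feature on two tested fragments (F1, F4) and one pool fragment (F5)
  feature <- data.frame(chrom = "chrT", start = c(100, 3100, 4100),
                        end = c(200, 3200, 4200))
  list(fragments = fragments, calls = calls, feature = feature,
       pool_ids = paste0("F", c(3, 5, 6, 7)),
       has_feature = c(F3 = FALSE, F5 = TRUE, F6 = FALSE, F7 = FALSE))
}

# enumerate every possible null subset of the toy pool
enrichment_toy_null <- function(toy, size = 3) {
  sets <- utils::combn(toy$pool_ids, size)
  apply(sets, 2, function(s) sum(toy$has_feature[s]))
}
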