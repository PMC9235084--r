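## Stratum-adjusted correlation coefficient (SCC) between two contact
## matrices: per-diagonal-distance Pearson correlations combined with
## stratum weights, after light mean-filter smoothing. Used for replicate
## reproducibility and condition-vs-condition similarity.

#' Mean-filter smooth a contact matrix
#'
#' Each entry is replaced by the mean of the `(2h+1) x (2h+1)` neighborhood
#' clipped to the matrix (boundary cells are renormalized by the clipped
#' neighborhood size). `h = 0` is the identity. Smoothing is applied per
#' chromosome on the dense symmetric matrix.
#'
#' @param matrix a `contact_matrix`.
#' @param h half-window in bins.
#' @return a `contact_matrix` (entries may be non-integer).
#' @export
smooth_matrix <- function(matrix, h) {
  stopifnot(inherits(matrix, "contact_matrix"), h >= 0)
  if (h == 0) return(matrix)
  blocks <- list()
  for (ch in unique(matrix$bins$chrom)) {
    blocks[[ch]] <- box_mean(cm_dense(matrix, ch), h)
  }
  cm_from_dense(blocks, matrix$bins)
}

# Clipped box-mean filter via a summed-area table.
box_mean <- function(M, h) {
  n <- nrow(M)
  A <- apply(M, 2, cumsum)
  S <- t(apply(A, 1, cumsum)) # S[i, j] = sum(M[1:i, 1:j])
  P <- matrix(0, n + 1, n + 1)
  P[-1, -1] <- S
  ri <- rep(seq_len(n), n)
  ci <- rep(seq_len(n), each = n)
  r1 <- pmax(ri - h, 1); r2 <- pmin(ri + h, n)
  c1 <- pmax(ci - h, 1); c2 <- pmin(ci + h, n)
  tot <- P[cbind(r2 + 1, c2 + 1)] - P[cbind(r1, c2 + 1)] -
    P[cbind(r2 + 1, c1)] + P[cbind(r1, c1)]
  cnt <- (r2 - r1 + 1) * (c2 - c1 + 1)
  matrix(tot / cnt, n, n)
}

#' Stratum-adjusted correlation coefficient between two contact matrices
#'
#' Both matrices are smoothed with [smooth_matrix()], then for each
#' diagonal distance `k` up to `max_dist` with at least 3 pairs and nonzero
#' variance in both matrices, the Pearson correlation `r_k` over paired
#' entries is computed. Strata are combined as `sum(w_k r_k) / sum(w_k)`
#' with `w_k = n_k * s_k(a) * s_k(b)` (`n_k` the pair count, `s_k` the
#' per-stratum standard deviation); zero-variance strata contribute weight
#' 0. Multi-chromosome input gives the pair-count-weighted mean of
#' per-chromosome SCCs.
#'
#' The SCC is symmetric in its arguments and invariant to scaling either
#' matrix by a positive constant.
#'
#' @param a,b `contact_matrix` objects on identical bin tables.
#' @param h smoothing half-window in bins (default 1).
#' @param max_dist maximum diagonal distance in bp (default 5 Mb).
#' @return an `scc_result`: `list(scc, per_stratum, h, max_dist)` with
#'   `per_stratum` a data.frame `chrom, distance, pearson_r, n_pairs,
#'   weight`.
#' @export
scc <- function(a, b, h = 1, max_dist = 5e6) {
  stopifnot(inherits(a, "contact_matrix"), inherits(b, "contact_matrix"))
  if (!identical(a$bins, b$bins)) stopf("contact matrices have mismatched bin tables")
  as_ <- smooth_matrix(a, h)
  bs_ <- smooth_matrix(b, h)
  strata <- list()
  per_chrom <- list()
  for (ch in unique(a$bins$chrom)) {
    A <- cm_dense(as_, ch)
    B <- cm_dense(bs_, ch)
    n <- nrow(A)
    bw <- median(a$bins$end[a$bins$chrom == ch] - a$bins$start[a$bins$chrom == ch])
    K <- min(n - 1, floor(max_dist / bw))
    wsum <- 0; wrsum <- 0; npairs <- 0
    for (k in 0:K) {
      ii <- seq_len(n - k)
      av <- A[cbind(ii, ii + k)]
      bv <- B[cbind(ii, ii + k)]
      n_k <- length(av)
      if (n_k < 3) next
      sa <- sd(av); sb <- sd(bv)
      if (sa == 0 || sb == 0) {
        strata[[length(strata) + 1]] <- data.frame(
          chrom = ch, distance = k * bw, pearson_r = NA_real_, n_pairs = n_k, weight = 0)
        next
      }
      r_k <- cor(av, bv)
      w_k <- n_k * sa * sb
      strata[[length(strata) + 1]] <- data.frame(
        chrom = ch, distance = k * bw, pearson_r = r_k, n_pairs = n_k, weight = w_k)
      wsum <- wsum + w_k
      wrsum <- wrsum + w_k * r_k
      npairs <- npairs + n_k
    }
    if (wsum > 0) {
      per_chrom[[ch]] <- c(scc = wrsum / wsum, n = npairs)
    }
  }
  if (length(per_chrom) == 0) stopf("no variable strata")
  pc <- do.call(rbind, per_chrom)
  out <- list(scc = sum(pc[, "scc"] * pc[, "n"]) / sum(pc[, "n"]),
              per_stratum = do.call(rbind, strata),
              h = h, max_dist = max_dist)
  class(out) <- "scc_result"
  out
}
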