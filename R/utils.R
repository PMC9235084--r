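## Internal helpers shared across modules. All genomic intervals in this
## package are 0-based half-open; GRanges conversion happens only at overlap
## time (GRanges is 1-based closed, hence the +1 on starts).

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Derive a reproducible sub-seed for a named generator stream
#'
#' Each synthetic-data operation draws from its own RNG stream keyed by
#' `(seed, op, extra)`, so adding a generator never shifts the output of
#' another one. The mixing is a small multiplicative hash over a Mersenne
#' prime; it only needs to decorrelate streams, not be cryptographic.
#'
#' @param seed integer master seed.
#' @param op character stream name (usually the operation name).
#' @param extra optional extra integer (e.g. a replicate number).
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, op, extra = 0) {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(op)) h <- (h * 31 + ch) %% m
  s <- abs(as.numeric(seed)) %% m
  s <- (s * 48271) %% m
  out <- (s + h + (abs(as.numeric(extra)) %% m) * 7919) %% m
  as.integer(out %% (m - 1) + 1)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Build a genome bin table
#'
#' Tiles each chromosome with fixed-width bins (the last bin of a chromosome
#' may be short). Indices are global, dense and 1-based, in file order.
#'
#' @param chrom_sizes named numeric vector, chromosome name -> length in bp.
#' @param bin_size bin width in bp.
#' @return data.frame with columns `chrom`, `start`, `end`, `index`.
#' @export
make_bins <- function(chrom_sizes, bin_size) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    stopf("chrom_sizes must be a named vector")
  }
  if (any(chrom_sizes < bin_size)) stopf("every chromosome must span at least one bin")
  out <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = ch, start = starts, end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, out)
  bins$index <- seq_len(nrow(bins))
  rownames(bins) <- NULL
  bins
}

# 0-based half-open data.frame -> GRanges
gr_from_df <- function(df) {
  GenomicRanges::GRanges(seqnames = df$chrom,
                         ranges = IRanges::IRanges(start = df$start + 1L,
                                                   end = df$end))
}

# Does each interval in `query` overlap (>= 1 bp) any interval in `subject`?
overlaps_any <- function(query, subject) {
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  GenomicRanges::countOverlaps(gr_from_df(query), gr_from_df(subject)) > 0
}

# Value of a signal track at single bp positions. Positions not covered by
# any interval get value 0 and covered = FALSE; positions may be negative
# (always uncovered).
track_values_at <- function(track, chrom, pos) {
  n <- length(pos)
  val <- numeric(n)
  covered <- logical(n)
  ok <- pos >= 0
  if (any(ok)) {
    q <- GenomicRanges::GRanges(chrom[ok],
                                IRanges::IRanges(pos[ok] + 1, pos[ok] + 1))
    s <- gr_from_df(track)
    hit <- GenomicRanges::findOverlaps(q, s, select = "first")
    val[ok][!is.na(hit)] <- track$value[hit[!is.na(hit)]]
    covered[ok] <- !is.na(hit)
  }
  list(value = val, covered = covered)
}

# Overlap-weighted mean of a signal track within each bin (0 where no
# coverage). Used to orient compartment eigenvectors.
bin_reference_values <- function(track, bins) {
  out <- numeric(nrow(bins))
  if (nrow(track) == 0) return(out)
  qb <- gr_from_df(bins)
  st <- gr_from_df(track)
  hits <- GenomicRanges::findOverlaps(qb, st)
  if (length(hits) == 0) return(out)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  w <- IRanges::width(IRanges::pintersect(IRanges::ranges(qb)[qi],
                                          IRanges::ranges(st)[si]))
  num <- tapply(w * track$value[si], qi, sum)
  den <- tapply(w, qi, sum)
  idx <- as.integer(names(num))
  out[idx] <- as.numeric(num) / as.numeric(den)
  out
}
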