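## Readers and writers for every on-disk format the pipeline touches, with
## strict validation and bit-exact round-trips. All formats are plain text:
## BED / bedGraph (0-based half-open, consumed natively), GMT, triplet
## contact matrix + bin BED (the HiC-Pro sparse dialect, 1-based global bin
## indices), interaction TSV (bait_id, otherend_id, score) and long-format
## abundance TSV (protein_id, group, wt1, wt2, dko1, dko2).

# ---- contact matrix container ------------------------------------------

#' Construct a binned contact matrix
#'
#' Sparse symmetric container for intrachromosomal contact counts. Only the
#' upper triangle (`i <= j`, diagonal allowed) is stored; a query for
#' `(j, i)` is by convention the stored `(i, j)` entry.
#'
#' @param bins bin table as from [make_bins()] (validated: contiguous,
#'   sorted, non-overlapping per chromosome; dense global 1-based `index`).
#' @param entries data.frame with columns `i`, `j`, `count`; entries are
#'   normalized to `i <= j`.
#' @return an object of class `contact_matrix`.
#' @export
contact_matrix <- function(bins, entries) {
  validate_bins(bins)
  if (nrow(entries) > 0) {
    if (any(!is.finite(entries$count)) || any(entries$count < 0)) {
      stopf("contact counts must be finite and non-negative")
    }
    bad <- entries$i < 1 | entries$i > nrow(bins) |
      entries$j < 1 | entries$j > nrow(bins)
    if (any(bad)) stopf("matrix entry %d references a bin index out of range", which(bad)[1])
    swap <- entries$i > entries$j
    if (any(swap)) {
      tmp <- entries$i[swap]
      entries$i[swap] <- entries$j[swap]
      entries$j[swap] <- tmp
    }
    key <- paste(entries$i, entries$j)
    if (anyDuplicated(key)) stopf("duplicate matrix entry for bin pair (%s)", key[duplicated(key)][1])
    entries <- entries[order(entries$i, entries$j), c("i", "j", "count")]
    rownames(entries) <- NULL
  } else {
    entries <- data.frame(i = integer(), j = integer(), count = numeric())
  }
  structure(list(bins = bins, entries = entries), class = "contact_matrix")
}

validate_bins <- function(bins, where = "bins") {
  need <- c("chrom", "start", "end", "index")
  if (!all(need %in% names(bins))) stopf("%s must have columns %s", where, paste(need, collapse = ", "))
  if (any(bins$start >= bins$end)) {
    stopf("%s: start >= end at line %d", where, which(bins$start >= bins$end)[1])
  }
  if (!identical(as.integer(bins$index), seq_len(nrow(bins)))) {
    stopf("%s: bin indices must be dense and in file order (1..n)", where)
  }
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    if (is.unsorted(b$start, strictly = TRUE)) stopf("%s: bins not sorted on %s", where, ch)
    if (nrow(b) > 1) {
      gap <- which(b$start[-1] != b$end[-nrow(b)])
      if (length(gap)) {
        line <- as.integer(rownames(b))[gap[1] + 1]
        stopf("%s: bins not contiguous on %s (line %d)", where, ch, line)
      }
    }
  }
  invisible(bins)
}

# Dense symmetric matrix for one chromosome (local bin order).
cm_dense <- function(cm, chrom) {
  b <- cm$bins[cm$bins$chrom == chrom, , drop = FALSE]
  if (nrow(b) == 0) stopf("chromosome %s not present in bin table", chrom)
  off <- min(b$index) - 1L
  n <- nrow(b)
  e <- cm$entries
  keep <- e$i > off & e$i <= off + n & e$j > off & e$j <= off + n
  e <- e[keep, , drop = FALSE]
  M <- matrix(0, n, n)
  if (nrow(e)) {
    M[cbind(e$i - off, e$j - off)] <- e$count
    M[cbind(e$j - off, e$i - off)] <- e$count
  }
  M
}

# Rebuild a contact_matrix from per-chromosome dense blocks (upper triangle,
# zeros dropped).
cm_from_dense <- function(blocks, bins) {
  entries <- do.call(rbind, lapply(names(blocks), function(ch) {
    M <- blocks[[ch]]
    off <- min(bins$index[bins$chrom == ch]) - 1L
    ut <- which(upper.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
    if (nrow(ut) == 0) return(NULL)
    data.frame(i = ut[, 1] + off, j = ut[, 2] + off, count = M[ut])
  }))
  if (is.null(entries)) entries <- data.frame(i = integer(), j = integer(), count = numeric())
  contact_matrix(bins, entries)
}

# ---- triplet matrix + bin BED ------------------------------------------

#' Read / write a sparse contact matrix (triplet + bin BED convention)
#'
#' The bin file is 4-column BED-like (`chrom start end index`, 0-based
#' half-open, dense 1-based global indices in file order); the matrix file
#' is 3 whitespace-separated columns (`i j count`). Entries are normalized
#' so that `i <= j`; a write -> read round-trip is the identity.
#'
#' @param matrix_path,bins_path file paths.
#' @return [read_matrix()] returns a `contact_matrix`; [write_matrix()]
#'   returns the paths, invisibly.
#' @export
read_matrix <- function(matrix_path, bins_path) {
  bins <- tryCatch(
    read.table(bins_path, sep = "\t", header = FALSE,
               col.names = c("chrom", "start", "end", "index"),
               colClasses = c("character", "numeric", "numeric", "integer")),
    error = function(e) stopf("malformed bin file %s: %s", bins_path, conditionMessage(e)))
  rownames(bins) <- seq_len(nrow(bins))
  validate_bins(bins, where = basename(bins_path))
  ent <- tryCatch(
    read.table(matrix_path, header = FALSE,
               col.names = c("i", "j", "count"),
               colClasses = c("integer", "integer", "numeric")),
    error = function(e) stopf("malformed matrix file %s: %s", matrix_path, conditionMessage(e)))
  bad <- which(ent$count < 0 | !is.finite(ent$count))
  if (length(bad)) stopf("%s: negative or non-finite count at line %d", basename(matrix_path), bad[1])
  oob <- which(ent$i < 1 | ent$i > nrow(bins) | ent$j < 1 | ent$j > nrow(bins))
  if (length(oob)) stopf("%s: bin index out of range at line %d", basename(matrix_path), oob[1])
  contact_matrix(bins, ent)
}

#' @param cm a `contact_matrix`.
#' @rdname read_matrix
#' @export
write_matrix <- function(cm, matrix_path, bins_path) {
  stopifnot(inherits(cm, "contact_matrix"))
  write.table(cm$bins[, c("chrom", "start", "end", "index")], bins_path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(cm$entries, matrix_path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(matrix = matrix_path, bins = bins_path))
}

# ---- BED / bedGraph -----------------------------------------------------

#' Read / write interval formats (BED, bedGraph)
#'
#' BED is treated as 0-based half-open; 3 columns are required, a 5th
#' (or numeric 4th) column is taken as the score. bedGraph is 4-column with
#' a non-negative value; intervals must be sorted and non-overlapping
#' within each chromosome.
#'
#' @param path file path.
#' @return [read_bed()] a data.frame `chrom,start,end[,score]` (a peak
#'   set); [read_bedgraph()] a data.frame `chrom,start,end,value` (a signal
#'   track).
#' @export
read_bed <- function(path) {
  raw <- read_tab_lines(path, min_fields = 3)
  out <- data.frame(chrom = vapply(raw, `[`, "", 1),
                    start = as.numeric(vapply(raw, `[`, "", 2)),
                    end = as.numeric(vapply(raw, `[`, "", 3)),
                    stringsAsFactors = FALSE)
  nf <- lengths(raw)
  if (all(nf >= 5)) {
    out$score <- as.numeric(vapply(raw, `[`, "", 5))
  } else if (all(nf == 4)) {
    v4 <- suppressWarnings(as.numeric(vapply(raw, `[`, "", 4)))
    if (!anyNA(v4)) out$score <- v4
  }
  check_intervals(out, basename(path), allow_overlap = TRUE)
  out
}

#' @param peaks interval data.frame as returned by [read_bed()].
#' @rdname read_bed
#' @export
write_bed <- function(peaks, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score"), names(peaks))
  if ("score" %in% cols && !"name" %in% cols) {
    peaks$name <- "."
    cols <- c("chrom", "start", "end", "name", "score")
  }
  write.table(peaks[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname read_bed
#' @export
read_bedgraph <- function(path) {
  raw <- read_tab_lines(path, min_fields = 4)
  out <- data.frame(chrom = vapply(raw, `[`, "", 1),
                    start = as.numeric(vapply(raw, `[`, "", 2)),
                    end = as.numeric(vapply(raw, `[`, "", 3)),
                    value = as.numeric(vapply(raw, `[`, "", 4)),
                    stringsAsFactors = FALSE)
  if (anyNA(out$value) || any(out$value < 0)) {
    stopf("%s: negative or non-numeric value at line %d", basename(path),
          which(is.na(out$value) | out$value < 0)[1])
  }
  check_intervals(out, basename(path), allow_overlap = FALSE)
  out
}

#' @param track signal data.frame as returned by [read_bedgraph()].
#' @rdname read_bed
#' @export
write_bedgraph <- function(track, path) {
  write.table(track[, c("chrom", "start", "end", "value")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_tab_lines <- function(path, min_fields) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  raw <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(raw) < min_fields)
  if (length(short)) {
    stopf("%s: expected at least %d tab-separated fields at line %d",
          basename(path), min_fields, short[1])
  }
  raw
}

check_intervals <- function(df, where, allow_overlap) {
  if (anyNA(df$start) || anyNA(df$end)) {
    stopf("%s: non-numeric coordinate at line %d", where, which(is.na(df$start) | is.na(df$end))[1])
  }
  bad <- which(df$start >= df$end)
  if (length(bad)) stopf("%s: start >= end at line %d", where, bad[1])
  for (ch in unique(df$chrom)) {
    b <- df[df$chrom == ch, ]
    if (is.unsorted(b$start)) stopf("%s: intervals not sorted on %s", where, ch)
    if (!allow_overlap && nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)])) {
      stopf("%s: overlapping intervals on %s", where, ch)
    }
  }
  invisible(df)
}

# ---- restriction fragment map ------------------------------------------

#' Read / write a restriction fragment map
#'
#' 5-column BED-like file: `chrom start end fragment_id is_bait` (0/1).
#' Fragments must tile each chromosome without gaps or overlaps.
#'
#' @param path file path.
#' @return data.frame `chrom,start,end,fragment_id,is_bait`.
#' @export
read_fragments <- function(path) {
  raw <- read_tab_lines(path, min_fields = 5)
  out <- data.frame(chrom = vapply(raw, `[`, "", 1),
                    start = as.numeric(vapply(raw, `[`, "", 2)),
                    end = as.numeric(vapply(raw, `[`, "", 3)),
                    fragment_id = vapply(raw, `[`, "", 4),
                    is_bait = vapply(raw, `[`, "", 5) == "1",
                    stringsAsFactors = FALSE)
  check_intervals(out, basename(path), allow_overlap = FALSE)
  for (ch in unique(out$chrom)) {
    b <- out[out$chrom == ch, ]
    if (nrow(b) > 1 && any(b$start[-1] != b$end[-nrow(b)])) {
      stopf("%s: fragments do not tile %s (gap found)", basename(path), ch)
    }
  }
  if (anyDuplicated(out$fragment_id)) stopf("%s: duplicate fragment_id", basename(path))
  out
}

#' @param fragments fragment map data.frame.
#' @rdname read_fragments
#' @export
write_fragments <- function(fragments, path) {
  df <- fragments[, c("chrom", "start", "end", "fragment_id")]
  df$is_bait <- as.integer(fragments$is_bait)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- interaction calls --------------------------------------------------

#' Read / write promoter-capture interaction calls
#'
#' Header TSV with columns `bait_id`, `otherend_id`, `score` (a CHiCAGO-style
#' confidence score, finite and >= 0). Every id must exist in the fragment
#' map and every bait must carry the bait flag.
#'
#' @param path file path.
#' @param fragments fragment map, as from [read_fragments()].
#' @return data.frame `bait_id,otherend_id,score`.
#' @export
read_interactions <- function(path, fragments) {
  out <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) stopf("malformed interaction file %s: %s", basename(path), conditionMessage(e)))
  need <- c("bait_id", "otherend_id", "score")
  if (!all(need %in% names(out))) stopf("%s: missing columns %s", basename(path),
                                        paste(setdiff(need, names(out)), collapse = ", "))
  out <- out[, need]
  unknown <- !(out$bait_id %in% fragments$fragment_id) |
    !(out$otherend_id %in% fragments$fragment_id)
  if (any(unknown)) {
    stopf("%s: interaction references unknown fragment at line %d", basename(path), which(unknown)[1] + 1)
  }
  bait_ok <- fragments$is_bait[match(out$bait_id, fragments$fragment_id)]
  if (any(!bait_ok)) stopf("%s: bait without bait flag at line %d", basename(path), which(!bait_ok)[1] + 1)
  if (any(!is.finite(out$score)) || any(out$score < 0)) {
    stopf("%s: scores must be finite and non-negative", basename(path))
  }
  out
}

#' @param calls interaction data.frame.
#' @rdname read_interactions
#' @export
write_interactions <- function(calls, path) {
  write.table(calls[, c("bait_id", "otherend_id", "score")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# ---- ChIP-MS abundance tables ------------------------------------------

#' Read / write label-free ChIP-MS abundance tables
#'
#' Long-format header TSV, one row per protein per experiment group, with
#' columns `protein_id, group, wt1, wt2, dko1, dko2` (all abundances finite
#' and >= 0). Column naming in third-party exports varies, so a
#' `column_map` (internal name -> file column name) may be supplied. No
#' ratios are computed at parse time: a row with `dko1 = dko2 = 0` parses
#' as-is.
#'
#' @param path file path.
#' @param column_map optional named character vector mapping internal
#'   column names to the names used in the file.
#' @return data.frame `protein_id,group,wt1,wt2,dko1,dko2`.
#' @export
read_abundance <- function(path, column_map = NULL) {
  out <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) stopf("malformed abundance file %s: %s", basename(path), conditionMessage(e)))
  need <- c("protein_id", "group", "wt1", "wt2", "dko1", "dko2")
  if (!is.null(column_map)) {
    for (internal in names(column_map)) {
      if (!column_map[[internal]] %in% names(out)) {
        stopf("%s: mapped column %s not found", basename(path), column_map[[internal]])
      }
      names(out)[names(out) == column_map[[internal]]] <- internal
    }
  }
  if (!all(need %in% names(out))) {
    stopf("%s: missing columns %s", basename(path), paste(setdiff(need, names(out)), collapse = ", "))
  }
  out <- out[, need]
  ab <- as.matrix(out[, c("wt1", "wt2", "dko1", "dko2")])
  if (any(!is.finite(ab)) || any(ab < 0)) {
    stopf("%s: abundances must be finite and non-negative (line %d)", basename(path),
          which(apply(!is.finite(ab) | ab < 0, 1, any))[1] + 1)
  }
  out
}

#' @param records abundance data.frame.
#' @rdname read_abundance
#' @export
write_abundance <- function(records, path) {
  write.table(records[, c("protein_id", "group", "wt1", "wt2", "dko1", "dko2")],
              path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# ---- GMT annotation sets ------------------------------------------------

#' Read / write GO annotation in GMT format
#'
#' One term per line: `term_id <tab> term_name <tab> member1 <tab> ...`.
#' Member sets must be non-empty.
#'
#' @param path file path.
#' @return a named list; each element is `list(name =, members =)`.
#' @export
read_gmt <- function(path) {
  raw <- read_tab_lines(path, min_fields = 3)
  ids <- vapply(raw, `[`, "", 1)
  if (anyDuplicated(ids)) stopf("%s: duplicate term id %s", basename(path), ids[duplicated(ids)][1])
  out <- lapply(raw, function(f) list(name = f[2], members = unique(f[-(1:2)])))
  names(out) <- ids
  out
}

#' @param annotation named list as returned by [read_gmt()].
#' @rdname read_gmt
#' @export
write_gmt <- function(annotation, path) {
  lines <- vapply(names(annotation), function(id) {
    t <- annotation[[id]]
    paste(c(id, t$name, t$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
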