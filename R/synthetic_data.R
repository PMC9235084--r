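## Synthetic-data generators with planted ground truth. Every downstream
## stage of the pipeline (compartment scoring, SCC, TAD calling, PIR
## enrichment, partner selection, ORA) is exercised on these objects in the
## test suite, so each generator plants exactly the statistical structure
## the corresponding analysis assumes and exposes the truth for recovery
## checks. One RNG stream per operation, derived from (seed, op-name), so
## adding a generator never shifts another generator's output.

#' Simulation configuration
#'
#' All knobs for the synthetic genome, Hi-C, ChIP-seq, promoter-capture and
#' ChIP-MS generators, with defaults chosen to emulate the study conditions
#' the pipeline targets: 25 kb bins, an A-compartment fraction near 4:5
#' (A:B ~ 0.8), megabase-scale compartment blocks, contact decay exponent 1
#' with checkerboard strength 0.6, TADs of mean size 750 kb boosted 3-fold,
#' peaks with 4:1 odds of landing in A bins, capture interactions confined
#' to 1 Mb of their bait, and a 16-sample-style WT/DKO abundance design in
#' which planted partners are absent from DKO.
#'
#' @param chrom_sizes named vector, chromosome -> length (bp).
#' @param bin_size Hi-C bin width (bp).
#' @param a_fraction target fraction of the genome in the A compartment.
#' @param mean_block_len mean compartment block length (bp); block lengths
#'   are geometric (memoryless), A and B means scaled so the stationary A
#'   fraction equals `a_fraction`.
#' @param compartment_strength checkerboard strength `kappa` in `[0, 1]`:
#'   contact means are multiplied by `1 + kappa * s_i * s_j` with `s = +1`
#'   (A) / `-1` (B).
#' @param decay_exponent distance-decay exponent `alpha > 0`: contact means
#'   fall off as `(|i - j| + 1)^-alpha` in bins.
#' @param depth expected contact count per bin (sets the Poisson scale so
#'   the mean marginal count per bin is about `depth`).
#' @param overdispersion optional negative-binomial overdispersion; 0 keeps
#'   pure Poisson counts.
#' @param tad_mean_size mean planted TAD size (bp).
#' @param tad_boost within-TAD contact multiplier `tau >= 1`.
#' @param peak_count,peak_width number and width (bp) of simulated peaks.
#' @param peak_a_enrichment odds multiplier `e` for placing a peak in an A
#'   bin versus a B bin (`Inf` = all peaks in A).
#' @param signal_noise_sd sd of the non-negative noise added to the per-bin
#'   peak-coverage signal track.
#' @param n_fragments restriction fragments per chromosome.
#' @param n_baits total bait fragments across the genome.
#' @param calls_per_bait expected interaction calls emitted per bait.
#' @param feature_fold planted other-end feature enrichment `phi` (ratio of
#'   feature probability at other-ends vs background fragments).
#' @param feature_base_rate background per-fragment feature probability.
#' @param min_call_dist,max_call_dist bait/other-end midpoint distance range
#'   (bp); very proximal pairs are never emitted, as in capture pipelines
#'   that discard re-ligation products.
#' @param n_proteins,partner_fraction ChIP-MS table size and planted
#'   partner fraction.
#' @param abundance_location,abundance_scale log-abundance (lognormal)
#'   location and scale.
#' @param replicate_noise_sd replicate-to-replicate lognormal noise sd on
#'   the log scale.
#' @param dropout_rate probability of zeroing a WT abundance cell of a
#'   non-partner (partners are never dropped, so planted truth stays
#'   recoverable).
#' @param partner_leak DKO abundance of planted partners (0 = absent).
#' @param n_go_terms,n_enriched_terms,go_term_size,go_partner_weight GO
#'   annotation generator: number of null terms, number of planted enriched
#'   terms, member-count range, and the sampling weight of partner proteins
#'   inside enriched terms.
#' @param seed master integer seed; fully determines all generator output.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(chrom_sizes = c(chrSynA = 20e6, chrSynB = 15e6),
                       bin_size = 25000,
                       a_fraction = 0.444,
                       mean_block_len = 1e6,
                       compartment_strength = 0.6,
                       decay_exponent = 1.0,
                       depth = 600,
                       overdispersion = 0,
                       tad_mean_size = 7.5e5,
                       tad_boost = 3,
                       peak_count = 2000,
                       peak_width = 400,
                       peak_a_enrichment = 4,
                       signal_noise_sd = 0.25,
                       n_fragments = 2500,
                       n_baits = 150,
                       calls_per_bait = 8,
                       feature_fold = 2,
                       feature_base_rate = 0.1,
                       min_call_dist = 10000,
                       max_call_dist = 1e6,
                       n_proteins = 1000,
                       partner_fraction = 0.05,
                       abundance_location = 14,
                       abundance_scale = 1,
                       replicate_noise_sd = 0.3,
                       dropout_rate = 0.1,
                       partner_leak = 0,
                       n_go_terms = 40,
                       n_enriched_terms = 3,
                       go_term_size = c(10, 50),
                       go_partner_weight = 25,
                       seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    if (a_fraction < 0 || a_fraction > 1) stopf("a_fraction must be in [0, 1]")
    if (partner_fraction < 0 || partner_fraction > 1) stopf("partner_fraction must be in [0, 1]")
    if (dropout_rate < 0 || dropout_rate > 1) stopf("dropout_rate must be in [0, 1]")
    if (compartment_strength < 0 || compartment_strength > 1) {
      stopf("compartment_strength must be in [0, 1] (contact means must stay non-negative)")
    }
    if (decay_exponent <= 0) stopf("decay_exponent must be > 0")
    if (tad_boost < 1) stopf("tad_boost must be >= 1")
    if (feature_fold < 1) stopf("feature_fold must be >= 1")
    if (!is.infinite(peak_a_enrichment) && peak_a_enrichment < 1) {
      stopf("peak_a_enrichment must be >= 1 (or Inf)")
    }
    if (feature_fold * feature_base_rate > 0.95) {
      stopf("feature_fold * feature_base_rate must stay below 0.95")
    }
    if (n_baits > n_fragments * length(chrom_sizes)) stopf("n_baits exceeds total fragments")
  })
  structure(cfg, class = "sim_config")
}

#' Plant compartment and TAD ground truth
#'
#' Draws alternating A/B compartment blocks along each chromosome with
#' geometric block lengths (mean `a_fraction * 2 * mean_block_len` for A
#' runs and `(1 - a_fraction) * 2 * mean_block_len` for B runs, so the
#' long-run A fraction converges to `a_fraction`), plus a planted TAD
#' partition with geometric sizes around `tad_mean_size`.
#'
#' @param config a [sim_config()].
#' @return an object of class `ground_truth`: `bins`, per-bin `labels`
#'   ("A"/"B"), `boundaries` (`b2a` and `a2b` data.frames of bin index and
#'   bp position), and `tad_intervals` (global bin-index spans).
#' @export
simulate_compartment_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  bins <- make_bins(config$chrom_sizes, config$bin_size)
  with_seed(derive_seed(config$seed, "compartment_truth"), {
    labels <- character(nrow(bins))
    tads <- list()
    mean_a <- max(1, config$a_fraction * 2 * config$mean_block_len / config$bin_size)
    mean_b <- max(1, (1 - config$a_fraction) * 2 * config$mean_block_len / config$bin_size)
    mean_tad <- max(2, config$tad_mean_size / config$bin_size)
    for (ch in names(config$chrom_sizes)) {
      idx <- bins$index[bins$chrom == ch]
      n <- length(idx)
      # compartment blocks
      if (config$a_fraction == 1) {
        lab <- rep("A", n)
      } else if (config$a_fraction == 0) {
        lab <- rep("B", n)
      } else {
        lab <- character(n)
        cur <- if (runif(1) < config$a_fraction) "A" else "B"
        pos <- 1
        while (pos <= n) {
          m <- if (cur == "A") mean_a else mean_b
          len <- 1 + rgeom(1, 1 / m)
          lab[pos:min(n, pos + len - 1)] <- cur
          pos <- pos + len
          cur <- if (cur == "A") "B" else "A"
        }
      }
      labels[idx] <- lab
      # planted TAD partition (tiles the chromosome)
      pos <- 1
      while (pos <= n) {
        len <- max(2, 1 + rgeom(1, 1 / mean_tad))
        tads[[length(tads) + 1]] <- data.frame(
          chrom = ch, start_bin = idx[pos], end_bin = idx[min(n, pos + len - 1)])
        pos <- pos + len
      }
    }
    truth <- structure(list(bins = bins, labels = labels,
                            boundaries = label_boundaries(bins, labels),
                            tad_intervals = do.call(rbind, tads)),
                       class = "ground_truth")
    truth
  })
}

# Boundaries implied by a label vector: a B->A boundary is the start
# coordinate of the first A bin of each A run whose left neighbor is B.
label_boundaries <- function(bins, labels) {
  b2a <- list(); a2b <- list()
  for (ch in unique(bins$chrom)) {
    idx <- bins$index[bins$chrom == ch]
    lab <- labels[idx]
    keep <- !is.na(lab)
    li <- idx[keep]; ll <- lab[keep]
    if (length(ll) < 2) next
    for (t in 2:length(ll)) {
      if (ll[t - 1] == "B" && ll[t] == "A") {
        b2a[[length(b2a) + 1]] <- data.frame(chrom = ch, index = li[t],
                                             pos = bins$start[li[t]])
      } else if (ll[t - 1] == "A" && ll[t] == "B") {
        a2b[[length(a2b) + 1]] <- data.frame(chrom = ch, index = li[t],
                                             pos = bins$start[li[t]])
      }
    }
  }
  empty <- data.frame(chrom = character(), index = integer(), pos = numeric())
  list(b2a = if (length(b2a)) do.call(rbind, b2a) else empty,
       a2b = if (length(a2b)) do.call(rbind, a2b) else empty)
}

#' Simulate a binned Hi-C contact matrix from planted truth
#'
#' Counts at bin pair `(i, j)` are Poisson (or negative binomial when
#' `overdispersion > 0`) with mean proportional to
#' `(|i - j| + 1)^-alpha * (1 + kappa * s_i * s_j) * (tau if same TAD)`,
#' scaled so the mean marginal count per bin is about `depth`. Only the
#' intrachromosomal upper triangle is stored; the matrix is symmetric by
#' construction.
#'
#' @param truth a `ground_truth` from [simulate_compartment_truth()].
#' @param config the same [sim_config()].
#' @param replicate_seed integer distinguishing biological/technical
#'   replicates drawn from the same truth.
#' @return a `contact_matrix`.
#' @export
simulate_contact_matrix <- function(truth, config, replicate_seed = 1) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  bins <- truth$bins
  s <- ifelse(truth$labels == "A", 1, -1)
  tad_id <- integer(nrow(bins))
  for (k in seq_len(nrow(truth$tad_intervals))) {
    t <- truth$tad_intervals[k, ]
    tad_id[t$start_bin:t$end_bin] <- k
  }
  with_seed(derive_seed(config$seed, "contact_matrix", replicate_seed), {
    blocks <- list()
    for (ch in names(config$chrom_sizes)) {
      idx <- bins$index[bins$chrom == ch]
      n <- length(idx)
      d <- abs(outer(seq_len(n), seq_len(n), "-"))
      mu <- (d + 1)^(-config$decay_exponent) *
        (1 + config$compartment_strength * outer(s[idx], s[idx]))
      same_tad <- outer(tad_id[idx], tad_id[idx], "==") & tad_id[idx] > 0
      mu[same_tad] <- mu[same_tad] * config$tad_boost
      ut <- upper.tri(mu, diag = TRUE)
      c0 <- (n * config$depth / 2) / sum(mu[ut])
      lam <- c0 * mu[ut]
      counts <- if (config$overdispersion > 0) {
        rnbinom(length(lam), mu = lam, size = 1 / config$overdispersion)
      } else {
        rpois(length(lam), lam)
      }
      M <- matrix(0, n, n)
      M[ut] <- counts
      M <- M + t(M) - diag(diag(M))
      blocks[[ch]] <- M
    }
    cm_from_dense(blocks, bins)
  })
}

#' Simulate ChIP-seq peaks and a matching signal track
#'
#' Each peak's bin is chosen with probability proportional to
#' `peak_a_enrichment` for A bins versus 1 for B bins
#' (`peak_a_enrichment = Inf` forces all peaks into A). The signal track is
#' the per-bin count of peak midpoints plus non-negative half-normal noise.
#'
#' @inheritParams simulate_contact_matrix
#' @return `list(peaks =, signal =)`; peaks sorted 0-based half-open.
#' @export
simulate_peaks <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  bins <- truth$bins
  with_seed(derive_seed(config$seed, "peaks"), {
    w <- if (is.infinite(config$peak_a_enrichment)) {
      ifelse(truth$labels == "A", 1, 0)
    } else {
      ifelse(truth$labels == "A", config$peak_a_enrichment, 1)
    }
    if (config$peak_count > 0 && sum(w) == 0) stopf("no eligible bins for peak placement")
    if (config$peak_count > 0) {
      bin_of <- sample(nrow(bins), config$peak_count, replace = TRUE, prob = w)
      width <- min(config$peak_width, config$bin_size)
      off <- floor(runif(config$peak_count) * (bins$end[bin_of] - bins$start[bin_of] - width))
      peaks <- data.frame(chrom = bins$chrom[bin_of],
                          start = bins$start[bin_of] + off,
                          end = bins$start[bin_of] + off + width)
      peaks <- peaks[order(match(peaks$chrom, names(config$chrom_sizes)), peaks$start), ]
      rownames(peaks) <- NULL
      cover <- tabulate(bin_of, nbins = nrow(bins))
    } else {
      peaks <- data.frame(chrom = character(), start = numeric(), end = numeric())
      cover <- numeric(nrow(bins))
    }
    signal <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                         value = cover + abs(rnorm(nrow(bins), 0, config$signal_noise_sd)))
    list(peaks = peaks, signal = signal)
  })
}

#' Simulate promoter-capture interaction calls with a planted feature
#'
#' Restriction fragments tile each chromosome (random cut sites); a random
#' subset of fragments become baits. Other-ends are sampled in cis within
#' `max_call_dist` of their bait with distance-decaying probability, and
#' every emitted call carries a confidence score >= 5. A feature peak set
#' is planted so that other-end fragments carry the feature with
#' probability `feature_fold * feature_base_rate` versus
#' `feature_base_rate` for background fragments, making the downstream
#' distance-matched fold estimate converge to `feature_fold`.
#'
#' @inheritParams simulate_contact_matrix
#' @return `list(fragments =, calls =, feature =)`.
#' @export
simulate_interactions <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "interactions"), {
    frags <- list()
    for (ch in names(config$chrom_sizes)) {
      len <- config$chrom_sizes[[ch]]
      cuts <- sort(unique(round(runif(config$n_fragments - 1, 1, len - 1))))
      bounds <- c(0, cuts, len)
      frags[[ch]] <- data.frame(chrom = ch, start = bounds[-length(bounds)],
                                end = bounds[-1])
    }
    fragments <- do.call(rbind, frags)
    rownames(fragments) <- NULL
    fragments$fragment_id <- sprintf("F%06d", seq_len(nrow(fragments)))
    fragments$is_bait <- FALSE
    fragments$is_bait[sample(nrow(fragments), min(config$n_baits, nrow(fragments)))] <- TRUE
    mid <- (fragments$start + fragments$end) / 2

    calls <- list()
    for (b in which(fragments$is_bait)) {
      dd <- abs(mid - mid[b])
      cand <- which(fragments$chrom == fragments$chrom[b] &
                      dd <= config$max_call_dist & dd >= config$min_call_dist)
      cand <- setdiff(cand, b)
      if (length(cand) == 0) next
      k <- min(length(cand), rpois(1, config$calls_per_bait))
      if (k == 0) next
      wts <- 1 / (abs(mid[cand] - mid[b]) + 50000)
      oe <- cand[sample.int(length(cand), k, prob = wts)]
      calls[[length(calls) + 1]] <- data.frame(
        bait_id = fragments$fragment_id[b],
        otherend_id = fragments$fragment_id[oe],
        score = 5 + rexp(k, 1))
    }
    calls <- if (length(calls)) do.call(rbind, calls) else
      data.frame(bait_id = character(), otherend_id = character(), score = numeric())
    rownames(calls) <- NULL

    is_oe <- fragments$fragment_id %in% calls$otherend_id
    p <- ifelse(is_oe, config$feature_fold * config$feature_base_rate,
                config$feature_base_rate)
    has <- runif(nrow(fragments)) < p
    fw <- pmin(200, floor((fragments$end - fragments$start) / 2))
    feature <- data.frame(chrom = fragments$chrom[has],
                          start = floor(mid[has]) - floor(fw[has] / 2),
                          end = floor(mid[has]) + pmax(1, ceiling(fw[has] / 2)))
    feature <- feature[order(match(feature$chrom, names(config$chrom_sizes)), feature$start), ]
    rownames(feature) <- NULL
    list(fragments = fragments, calls = calls, feature = feature)
  })
}

#' Simulate a WT/DKO ChIP-MS abundance table with planted partners
#'
#' Planted partners (a fixed random subset of proteins shared by every
#' group, drawn from a group-independent stream) get lognormal WT
#' abundances in both replicates and `partner_leak` (default 0: absent) in
#' both DKO replicates, so the WT/DKO average ratio always clears the
#' selection threshold. Non-partners get WT ~= DKO lognormal draws with
#' replicate noise; `dropout_rate` zeroes WT cells of non-partners only.
#'
#' @param config a [sim_config()].
#' @param group_label experiment group (e.g. `"MEF_N1"`); determines the
#'   abundance noise stream but not the planted partner identities.
#' @return `list(records =, partner_ids =)`.
#' @export
simulate_abundance_table <- function(config, group_label) {
  stopifnot(inherits(config, "sim_config"))
  proteins <- sprintf("P%05d", seq_len(config$n_proteins))
  n_partner <- round(config$partner_fraction * config$n_proteins)
  if (n_partner < 1) warnf("no partners planted (partner_fraction * n_proteins < 1)")
  partners <- with_seed(derive_seed(config$seed, "abundance_partners"),
                        sort(sample(proteins, n_partner)))
  with_seed(derive_seed(config$seed, paste0("abundance_", group_label)), {
    n <- config$n_proteins
    base <- rlnorm(n, config$abundance_location, config$abundance_scale)
    noise <- function() rlnorm(n, 0, config$replicate_noise_sd)
    wt1 <- base * noise(); wt2 <- base * noise()
    dko1 <- base * noise(); dko2 <- base * noise()
    is_p <- proteins %in% partners
    dko1[is_p] <- config$partner_leak
    dko2[is_p] <- config$partner_leak
    if (config$dropout_rate > 0) {
      wt1[!is_p & runif(n) < config$dropout_rate] <- 0
      wt2[!is_p & runif(n) < config$dropout_rate] <- 0
    }
    records <- data.frame(protein_id = proteins, group = group_label,
                          wt1 = wt1, wt2 = wt2, dko1 = dko1, dko2 = dko2,
                          stringsAsFactors = FALSE)
    list(records = records, partner_ids = partners)
  })
}

#' Simulate a GO annotation with planted enriched terms
#'
#' Emits `n_go_terms` null terms (uniform random member sets from the
#' universe) plus `n_enriched_terms` planted terms whose members are drawn
#' with weight `go_partner_weight` from the partner set versus 1 from the
#' rest of the universe.
#'
#' @param config a [sim_config()].
#' @param partners,universe protein id sets, `partners` a subset of
#'   `universe`.
#' @return `list(annotation =, enriched_terms =)`; the annotation is a
#'   named list in the [read_gmt()] shape.
#' @export
simulate_go_annotation <- function(config, partners, universe) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(partners %in% universe)) stopf("partners must be a subset of the universe")
  with_seed(derive_seed(config$seed, "go_annotation"), {
    ann <- list()
    sizes <- sample(config$go_term_size[1]:config$go_term_size[2],
                    config$n_go_terms + config$n_enriched_terms, replace = TRUE)
    for (k in seq_len(config$n_go_terms)) {
      id <- sprintf("GO:SYN%04d", k)
      ann[[id]] <- list(name = sprintf("synthetic null process %d", k),
                        members = sample(universe, min(sizes[k], length(universe))))
    }
    w <- ifelse(universe %in% partners, config$go_partner_weight, 1)
    enriched <- character(config$n_enriched_terms)
    for (k in seq_len(config$n_enriched_terms)) {
      id <- sprintf("GO:SYNE%03d", k)
      enriched[k] <- id
      sz <- min(sizes[config$n_go_terms + k], length(universe))
      ann[[id]] <- list(name = sprintf("synthetic enriched process %d", k),
                        members = universe[sample.int(length(universe), sz, prob = w)])
    }
    list(annotation = ann, enriched_terms = enriched)
  })
}

#' Write a complete synthetic dataset to a directory
#'
#' Runs every generator under one config and writes each object through the
#' standard format writers (triplet matrix + bin BED for three replicate
#' matrices, peak BED, signal bedGraph, fragment map, interaction TSV,
#' feature BED, four-group abundance TSV, GMT annotation), plus
#' tab-separated ground-truth sidecars (per-bin labels, boundaries, TAD
#' spans, partner ids, enriched term ids).
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if missing).
#' @param groups experiment group labels for the abundance tables.
#' @return invisibly, a named list of everything generated.
#' @export
simulate_dataset <- function(config, dir,
                             groups = c("ES_N1", "ES_N2", "MEF_N1", "MEF_N2")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  truth <- simulate_compartment_truth(config)
  mats <- list(wt_rep1 = simulate_contact_matrix(truth, config, replicate_seed = 1),
               wt_rep2 = simulate_contact_matrix(truth, config, replicate_seed = 2),
               dko_rep1 = simulate_contact_matrix(truth, config, replicate_seed = 3))
  for (nm in names(mats)) {
    write_matrix(mats[[nm]], p(paste0(nm, ".matrix")), p(paste0(nm, ".bins.bed")))
  }
  pk <- simulate_peaks(truth, config)
  write_bed(pk$peaks, p("peaks.bed"))
  write_bedgraph(pk$signal, p("signal.bedgraph"))
  ints <- simulate_interactions(truth, config)
  write_fragments(ints$fragments, p("fragments.bed"))
  write_interactions(ints$calls, p("interactions.tsv"))
  write_bed(ints$feature, p("feature.bed"))
  ab <- lapply(groups, function(g) simulate_abundance_table(config, g))
  names(ab) <- groups
  records <- do.call(rbind, lapply(ab, `[[`, "records"))
  rownames(records) <- NULL
  write_abundance(records, p("abundance.tsv"))
  go <- simulate_go_annotation(config, ab[[1]]$partner_ids,
                               sprintf("P%05d", seq_len(config$n_proteins)))
  write_gmt(go$annotation, p("annotation.gmt"))
  # ground-truth sidecars
  write.table(data.frame(truth$bins, label = truth$labels), p("truth_labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth$boundaries$b2a, p("truth_boundaries_b2a.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth$tad_intervals, p("truth_tads.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(ab[[1]]$partner_ids, p("truth_partners.txt"))
  writeLines(go$enriched_terms, p("truth_enriched_terms.txt"))
  invisible(list(truth = truth, matrices = mats, peaks = pk, interactions = ints,
                 abundance = ab, go = go, dir = dir))
}
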