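# Generators: determinism, planted-structure statistics, stream isolation.

test_that("generators are bit-identical under the same seed and isolated across ops", {
  cfg <- small_cfg(seed = 42)
  t1 <- simulate_compartment_truth(cfg)
  t2 <- simulate_compartment_truth(cfg)
  expect_identical(t1, t2)
  expect_identical(simulate_contact_matrix(t1, cfg, 1), simulate_contact_matrix(t1, cfg, 1))
  expect_false(identical(simulate_contact_matrix(t1, cfg, 1),
                         simulate_contact_matrix(t1, cfg, 2)))
  expect_identical(simulate_peaks(t1, cfg), simulate_peaks(t1, cfg))
  expect_identical(simulate_interactions(t1, cfg), simulate_interactions(t1, cfg))
  expect_identical(simulate_abundance_table(cfg, "ES_N1"),
                   simulate_abundance_table(cfg, "ES_N1"))
  ann <- simulate_go_annotation(cfg, sprintf("P%05d", 1:10), sprintf("P%05d", 1:300))
  expect_identical(ann, simulate_go_annotation(cfg, sprintf("P%05d", 1:10),
                                               sprintf("P%05d", 1:300)))
  # drawing a contact matrix does not shift the peak stream
  pk_before <- simulate_peaks(t1, cfg)
  invisible(simulate_contact_matrix(t1, cfg, 7))
  expect_identical(pk_before, simulate_peaks(t1, cfg))
})

test_that("compartment truth converges to the target A fraction and handles degenerate fractions", {
  # Monte-Carlo over 10 000 replicate truths on a 10 Mb chromosome
  fracs <- vapply(seq_len(10000), function(s) {
    cfg <- sim_config(chrom_sizes = c(chrT = 10e6), a_fraction = 0.5, seed = s)
    mean(simulate_compartment_truth(cfg)$labels == "A")
  }, 0)
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - 0.5), 3 * se)

  cfg1 <- sim_config(chrom_sizes = c(chrT = 5e6), a_fraction = 1, seed = 1)
  t1 <- simulate_compartment_truth(cfg1)
  expect_true(all(t1$labels == "A"))
  expect_identical(nrow(t1$boundaries$b2a), 0L)
  expect_identical(nrow(t1$boundaries$a2b), 0L)
  cfg0 <- sim_config(chrom_sizes = c(chrT = 5e6), a_fraction = 0, seed = 1)
  expect_true(all(simulate_compartment_truth(cfg0)$labels == "B"))
})

test_that("truth boundaries and TAD intervals are internally consistent", {
  truth <- simulate_compartment_truth(small_cfg(seed = 9))
  # a boundary exists exactly where adjacent labels differ
  for (ch in unique(truth$bins$chrom)) {
    idx <- truth$bins$index[truth$bins$chrom == ch]
    lab <- truth$labels[idx]
    manual_b2a <- idx[which(lab[-1] == "A" & lab[-length(lab)] == "B") + 1]
    expect_identical(truth$boundaries$b2a$index[truth$boundaries$b2a$chrom == ch],
                     manual_b2a)
  }
  ti <- truth$tad_intervals
  expect_true(all(ti$start_bin <= ti$end_bin))
  ord <- order(ti$start_bin)
  expect_true(all(ti$start_bin[ord][-1] > ti$end_bin[ord][-nrow(ti)]))
})

test_that("contact counts are symmetric, integer and decay with the configured exponent", {
  cfg <- sim_config(chrom_sizes = c(chrT = 10e6), compartment_strength = 0,
                    tad_boost = 1, seed = 3)
  truth <- simulate_compartment_truth(cfg)
  m <- simulate_contact_matrix(truth, cfg, 1)
  expect_true(all(m$entries$i <= m$entries$j))
  expect_true(all(m$entries$count == round(m$entries$count)))
  M <- chromarch:::cm_dense(m, "chrT")
  expect_identical(M, t(M))
  # log-log regression of mean count against distance recovers -alpha
  d <- abs(row(M) - col(M))
  mean_by_d <- tapply(M[upper.tri(M)], d[upper.tri(M)], mean)
  dd <- as.numeric(names(mean_by_d))
  keep <- dd >= 1 & dd <= 100
  fit <- lm(log(mean_by_d[keep]) ~ log(dd[keep] + 1))
  expect_lt(abs(unname(coef(fit)[2]) + cfg$decay_exponent), 0.1)
})

test_that("checkerboard strength raises same-label contact means at matched distance", {
  cfg <- sim_config(chrom_sizes = c(chrT = 10e6), compartment_strength = 0.6,
                    tad_boost = 1, seed = 5)
  truth <- simulate_compartment_truth(cfg)
  M <- chromarch:::cm_dense(simulate_contact_matrix(truth, cfg, 1), "chrT")
  s <- truth$labels
  d <- abs(row(M) - col(M))
  same <- outer(s, s, "==")
  for (dd in c(20, 40, 60)) {
    sel <- d == dd
    expect_gt(mean(M[sel & same]), mean(M[sel & !same]))
  }
})

test_that("peak placement follows the A-bin odds and degenerate cases", {
  cfg <- small_cfg(seed = 2, peak_a_enrichment = Inf, peak_count = 500)
  truth <- simulate_compartment_truth(cfg)
  pk <- simulate_peaks(truth, cfg)
  mids <- floor((pk$peaks$start + pk$peaks$end) / 2)
  # all peak midpoints fall in A bins
  prof_bins <- truth$bins
  gr_hit <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(pk$peaks$chrom, IRanges::IRanges(mids + 1, mids + 1)),
    GenomicRanges::GRanges(prof_bins$chrom,
                           IRanges::IRanges(prof_bins$start + 1, prof_bins$end)),
    select = "first")
  expect_true(all(truth$labels[gr_hit] == "A"))

  cfg0 <- small_cfg(seed = 2, peak_count = 0, signal_noise_sd = 0)
  pk0 <- simulate_peaks(simulate_compartment_truth(cfg0), cfg0)
  expect_identical(nrow(pk0$peaks), 0L)
  expect_true(all(pk0$signal$value == 0))
})

test_that("interaction calls respect the distance window and carry confident scores", {
  cfg <- small_cfg(seed = 4)
  truth <- simulate_compartment_truth(cfg)
  ints <- simulate_interactions(truth, cfg)
  f <- ints$fragments
  # fragments tile each chromosome
  for (ch in unique(f$chrom)) {
    b <- f[f$chrom == ch, ]
    expect_identical(b$start[-1], b$end[-nrow(b)])
  }
  mid <- (f$start + f$end) / 2
  bi <- match(ints$calls$bait_id, f$fragment_id)
  oi <- match(ints$calls$otherend_id, f$fragment_id)
  expect_true(all(f$is_bait[bi]))
  expect_identical(f$chrom[bi], f$chrom[oi])
  d <- abs(mid[bi] - mid[oi])
  expect_true(all(d <= cfg$max_call_dist))
  expect_true(all(d >= cfg$min_call_dist))
  expect_true(all(ints$calls$score >= 5))
})

test_that("abundance tables plant recoverable partners with the configured design", {
  cfg <- small_cfg(seed = 6)
  ab <- simulate_abundance_table(cfg, "MEF_N1")
  expect_equal(length(ab$partner_ids), round(cfg$partner_fraction * cfg$n_proteins))
  # partner identities are shared across groups; abundances are not
  ab2 <- simulate_abundance_table(cfg, "MEF_N2")
  expect_identical(ab$partner_ids, ab2$partner_ids)
  expect_false(identical(ab$records$wt1, ab2$records$wt1))
  # noise-free planting: the filter recovers exactly the planted set
  cfg0 <- small_cfg(seed = 6, dropout_rate = 0, partner_leak = 0)
  ab0 <- simulate_abundance_table(cfg0, "MEF_N1")
  pc <- select_partners(ab0$records, threshold = 10)
  expect_setequal(pc$protein_id[pc$is_partner], ab0$partner_ids)
  # under default noise almost no non-partner clears a tenfold ratio
  pc_noisy <- select_partners(ab$records, threshold = 10)
  nonp <- !(pc_noisy$protein_id %in% ab$partner_ids)
  expect_lt(mean(pc_noisy$ratio[nonp] >= 10, na.rm = TRUE), 0.01)
  expect_warning(
    simulate_abundance_table(small_cfg(seed = 1, partner_fraction = 0.001), "ES_N1"),
    "no partners planted")
})

test_that("planted GO terms are strongly enriched in the partner set", {
  cfg <- small_cfg(seed = 8)
  universe <- sprintf("P%05d", seq_len(cfg$n_proteins))
  ab <- simulate_abundance_table(cfg, "ES_N1")
  go <- simulate_go_annotation(cfg, ab$partner_ids, universe)
  res <- ora(ab$partner_ids, universe, go$annotation)
  planted <- res[res$term_id %in% go$enriched_terms, ]
  expect_true(all(planted$q_value < 0.05))
})
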