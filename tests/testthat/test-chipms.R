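# Partner selection, threshold sweep, ORA and the four-group consensus.

test_that("the partner filter applies presence-in-both-WT and the inclusive ratio rule", {
  rec <- data.frame(protein_id = c("Pa", "Pb", "Pc", "Pd"), group = "MEF_N1",
                    wt1 = c(5, 0, 100, 100), wt2 = c(7, 100, 100, 100),
                    dko1 = c(0, 1, 10, 11), dko2 = c(0, 1, 10, 11))
  pc <- select_partners(rec, threshold = 10)
  # absent in DKO: infinite ratio, passes any finite threshold
  expect_true(pc$is_partner[1])
  expect_identical(pc$ratio[1], Inf)
  # one WT replicate zero disqualifies regardless of ratio
  expect_false(pc$is_partner[2])
  # ratio exactly 10 is a partner (>= is inclusive)
  expect_equal(pc$ratio[3], 10)
  expect_true(pc$is_partner[3])
  expect_false(pc$is_partner[4])

  # invariance to global abundance rescaling
  rec2 <- rec
  rec2[, 3:6] <- rec2[, 3:6] * 37.5
  expect_identical(select_partners(rec2, 10)$is_partner, pc$is_partner)

  expect_error(select_partners(rec[0, ]), "no abundance records")
  bad <- rec; bad$wt1[1] <- -1
  expect_error(select_partners(bad), "non-negative")
})

test_that("threshold sweep counts are monotone with strict handling of the top cut", {
  # hand-enumerable table: ratios Inf, 600, 500, 50, 12, 9, and one
  # zero-WT row; both pooling conventions computed by hand
  rec <- data.frame(
    protein_id = c("P1", "P2", "P3", "P4", "P5", "P6", "P7", "P1"),
    group = c(rep("ES_N1", 7), "MEF_N1"),
    wt1 = c(10, 600, 500, 50, 12, 9, 0, 20),
    wt2 = c(10, 600, 500, 50, 12, 9, 90, 20),
    dko1 = c(0, 1, 1, 1, 1, 1, 1, 1),
    dko2 = c(0, 1, 1, 1, 1, 1, 1, 1))
  sw <- threshold_sweep(rec, thresholds = c(10, 50, 500))
  # pairs passing >= 10: (P1,ES) Inf, (P2) 600, (P3) 500, (P4) 50, (P5) 12,
  # (P1,MEF) 20 -> 6; >= 50 drops P5 and (P1,MEF) -> 4; > 500 (strict)
  # keeps only Inf and 600 -> 2. Distinct proteins: 5 / 4 / 2.
  expect_equal(sw$n_protein_group, c(6, 4, 2))
  expect_equal(sw$n_proteins, c(5, 4, 2))
  expect_true(sw$strict[3])
  expect_false(any(sw$strict[1:2]))
  expect_true(all(diff(sw$n_protein_group) <= 0))

  # every DKO zero with positive WT pairs: identical counts at all thresholds
  allinf <- data.frame(protein_id = paste0("Q", 1:5), group = "ES_N1",
                       wt1 = 1:5, wt2 = 1:5, dko1 = 0, dko2 = 0)
  sw2 <- threshold_sweep(allinf)
  expect_true(all(sw2$n_protein_group == 5))
  expect_error(threshold_sweep(allinf[0, ]), "no abundance records")
  expect_error(threshold_sweep(allinf, thresholds = c(50, 10)), "ascending")
})

test_that("threshold sweep is monotone on random abundance tables", {
  for (s in 1:5) {
    cfg <- small_cfg(seed = s, dropout_rate = 0.2)
    rec <- do.call(rbind, lapply(c("ES_N1", "MEF_N1"), function(g)
      simulate_abundance_table(cfg, g)$records))
    sw <- threshold_sweep(rec, thresholds = c(2, 10, 50, 500),
                          strict = c(FALSE, FALSE, FALSE, TRUE))
    expect_true(all(diff(sw$n_protein_group) <= 0))
    expect_true(all(diff(sw$n_proteins) <= 0))
  }
})

test_that("ORA p-values agree with the hypergeometric closed form and handle edge terms", {
  universe <- paste0("U", 1:20)
  term5 <- universe[1:5]
  ann <- list(T1 = list(name = "exact", members = term5))
  res <- ora(term5, universe, ann)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p_value, 6.450e-05, tolerance = 1e-4)

  # zero overlap: enrichment 0, one-sided p = 1
  ann2 <- list(T1 = list(name = "miss", members = universe[6:10]))
  res2 <- ora(universe[1:5], universe, ann2)
  expect_equal(res2$enrichment_score, 0)
  expect_equal(res2$p_value, 1)

  # random small universes against the exhaustive closed form
  set.seed(71)
  for (rep in 1:20) {
    N <- sample(10:25, 1)
    uni <- paste0("G", seq_len(N))
    K <- sample(2:(N - 2), 1); n <- sample(2:(N - 2), 1)
    ann3 <- list(T = list(name = "t", members = sample(uni, K)))
    samp <- sample(uni, n)
    r <- ora(samp, uni, ann3)
    k <- length(intersect(samp, ann3$T$members))
    expect_equal(r$p_value, oracle_hyper_p(k, K, N, n), tolerance = 1e-12)
  }

  expect_error(ora(c("U1", "ZZZ"), universe, ann), "outside the universe")
  # terms with no universe overlap are skipped, not tested
  ann4 <- list(T1 = list(name = "in", members = universe[1:5]),
               T2 = list(name = "out", members = c("X1", "X2")))
  expect_identical(ora(universe[1:5], universe, ann4)$term_id, "T1")
})

test_that("BH adjustment orders results and bounds the false discovery proportion", {
  set.seed(72)
  universe <- paste0("G", 1:400)
  fdp <- vapply(1:25, function(rep) {
    enriched <- sample(universe, 60)
    ann <- c(
      lapply(1:15, function(i) list(name = "sig", members = sample(enriched, 25))),
      lapply(1:60, function(i) list(name = "null", members = sample(universe, 25))))
    names(ann) <- sprintf("T%03d", seq_along(ann))
    res <- ora(enriched, universe, ann, alpha = 0.05)
    called <- res$term_id[res$significant]
    if (!length(called)) return(0)
    mean(res$term_name[match(called, res$term_id)] == "null")
  }, 0)
  expect_lt(mean(fdp), 0.05 + 2 * sd(fdp) / sqrt(length(fdp)) + 0.02)
  # q >= p and the sort is by descending -log10(q)
  res <- ora(sample(universe, 50), universe, {
    ann <- lapply(1:30, function(i) list(name = "x", members = sample(universe, 20)))
    names(ann) <- sprintf("N%02d", 1:30); ann
  })
  expect_true(all(res$q_value >= res$p_value - 1e-15))
  expect_true(!is.unsorted(-res$neg_log10_q))
})

test_that("consensus requires significance in all four groups and tallies unique terms", {
  universe <- paste0("G", 1:300)
  groups <- c("ES_N1", "ES_N2", "MEF_N1", "MEF_N2")
  set.seed(73)
  shared <- sample(universe, 30)
  uniq <- lapply(1:4, function(i) sample(setdiff(universe, shared), 25))
  ann <- list(SHARED = list(name = "shared process", members = shared))
  for (i in 1:4) ann[[paste0("ONLY", i)]] <- list(name = paste("only", i),
                                                  members = uniq[[i]])
  for (j in 1:20) ann[[paste0("NULL", j)]] <- list(name = "null",
                                                   members = sample(universe, 20))
  res_by_group <- setNames(lapply(1:4, function(i) {
    samp <- unique(c(shared, uniq[[i]], sample(universe, 10)))
    ora(samp, universe, ann)
  }), groups)
  cons <- consensus_categories(res_by_group)
  expect_true("SHARED" %in% cons$consensus$term_id)
  expect_false(any(paste0("ONLY", 1:4) %in% cons$consensus$term_id))
  expect_true(all(cons$unique_by_group >= 1))

  # identical result lists: consensus equals each list's significant set
  same <- setNames(rep(res_by_group[1], 4), groups)
  cons2 <- consensus_categories(same)
  expect_setequal(cons2$consensus$term_id,
                  res_by_group[[1]]$term_id[res_by_group[[1]]$significant])
  expect_identical(cons2$n_unique, 0L)

  expect_error(consensus_categories(res_by_group[1:3]), "missing group")
})
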