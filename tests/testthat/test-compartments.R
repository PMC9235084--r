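# Compartment scoring: checkerboard separation, oracle equivalence,
# invariances, segmentation and boundary semantics.

test_that("a two-block matrix yields a clean A/B split oriented by the reference", {
  n <- 20
  M <- matrix(1, n, n)
  M[1:10, 1:10] <- 10
  M[11:20, 11:20] <- 10
  cm <- dense_to_cm(M)
  ref <- flat_track(cm$bins, value = c(rep(2, 10), rep(0, 10)))
  prof <- infer_cscores(cm, ref, min_bins = 5)
  expect_true(all(prof$label[1:10] == "A"))
  expect_true(all(prof$label[11:20] == "B"))
  expect_true(all(abs(prof$cscore) <= 1))
})

test_that("cscores match the dense eigendecomposition oracle", {
  # fixed 8-bin toy
  set.seed(81)
  M8 <- matrix(0, 8, 8)
  M8[upper.tri(M8, diag = TRUE)] <- rpois(36, 20)
  M8 <- M8 + t(M8) - diag(diag(M8))
  M8[1:4, 1:4] <- M8[1:4, 1:4] + 15
  M8[5:8, 5:8] <- M8[5:8, 5:8] + 15
  cm <- dense_to_cm(M8)
  ref <- flat_track(cm$bins, value = c(rep(1, 4), rep(0, 4)))
  got <- infer_cscores(cm, ref, min_bins = 2)$cscore
  want <- oracle_cscores(M8, c(rep(1, 4), rep(0, 4)))
  expect_lt(min(max(abs(got - want)), max(abs(got + want))), 1e-8)

  # random matrices up to 50 bins, with decay and a planted split
  for (s in 1:3) {
    set.seed(200 + s)
    n <- sample(25:50, 1)
    lab <- rep(c(1, -1), each = n / 2, length.out = n)
    mu <- 40 * (abs(outer(1:n, 1:n, "-")) + 1)^-1 * (1 + 0.5 * outer(lab, lab))
    M <- matrix(rpois(n * n, mu), n, n)
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    cm <- dense_to_cm(M)
    rv <- as.numeric(lab == 1)
    got <- infer_cscores(cm, flat_track(cm$bins, rv), min_bins = 2)$cscore
    want <- oracle_cscores(M, rv)
    expect_lt(min(max(abs(got - want)), max(abs(got + want))), 1e-8)
  }
})

test_that("degenerate matrices are rejected and scaling leaves scores unchanged", {
  cmc <- dense_to_cm(matrix(5, 12, 12))
  expect_error(infer_cscores(cmc, flat_track(cmc$bins), min_bins = 2), "no usable bins")

  cfg <- small_cfg(seed = 21)
  truth <- simulate_compartment_truth(cfg)
  m <- simulate_contact_matrix(truth, cfg, 1)
  ref <- simulate_peaks(truth, cfg)$signal
  m3 <- m
  m3$entries$count <- m3$entries$count * 3
  expect_equal(infer_cscores(m, ref)$cscore, infer_cscores(m3, ref)$cscore,
               tolerance = 1e-12)
})

test_that("segmentation merges label runs and reports the A:B length ratio", {
  bins <- make_bins(c(chrT = 5 * 25000), 25000)
  prof <- data.frame(bins, cscore = c(0.5, 0.4, -0.2, -0.3, -0.6),
                     label = c("A", "A", "B", "B", "B"))
  class(prof) <- c("compartment_profile", "data.frame")
  sr <- segment_and_ratio(prof)
  expect_equal(sr$segments$compartment, c("A", "B"))
  expect_equal(sr$segments$start, c(0, 50000))
  expect_equal(sr$segments$end, c(50000, 125000))
  expect_equal(sr$ab_ratio, 50000 / 75000)

  prof$label <- "A"
  prof$cscore <- 0.5
  expect_warning(sr2 <- segment_and_ratio(prof), "infinite")
  expect_identical(sr2$ab_ratio, Inf)
  expect_identical(nrow(sr2$segments), 1L)
})

test_that("boundary positions follow the labeled-neighbor rule, skipping masked bins", {
  bins <- make_bins(c(chrT = 4 * 25000), 25000)
  prof <- data.frame(bins, cscore = c(-1, -1, 1, 1), label = c("B", "B", "A", "A"))
  class(prof) <- c("compartment_profile", "data.frame")
  b <- find_boundaries(prof, "BtoA")
  expect_equal(b$pos, 50000)

  prof2 <- data.frame(make_bins(c(chrT = 3 * 25000), 25000),
                      cscore = c(1, -1, 1), label = c("A", "B", "A"))
  class(prof2) <- c("compartment_profile", "data.frame")
  expect_equal(nrow(find_boundaries(prof2, "BtoA")), 1L)
  expect_equal(find_boundaries(prof2, "BtoA")$pos, 50000)
  expect_equal(find_boundaries(prof2, "AtoB")$pos, 25000)

  # an NA run between B and A does not create extra boundaries; the A run
  # start is still reported because its nearest labeled left neighbor is B
  prof3 <- data.frame(make_bins(c(chrT = 5 * 25000), 25000),
                      cscore = c(-1, NA, NA, 1, 1),
                      label = c("B", NA, NA, "A", "A"))
  class(prof3) <- c("compartment_profile", "data.frame")
  b3 <- find_boundaries(prof3, "BtoA")
  expect_equal(b3$pos, 75000)
})

test_that("profile comparison is exact on identity and errors on mismatched bins", {
  cfg <- small_cfg(seed = 22)
  truth <- simulate_compartment_truth(cfg)
  m <- simulate_contact_matrix(truth, cfg, 1)
  ref <- simulate_peaks(truth, cfg)$signal
  prof <- infer_cscores(m, ref)
  cmp <- compare_profiles(prof, prof)
  expect_equal(cmp$pearson_r, 1)
  expect_identical(length(cmp$switched_bins), 0L)

  other <- infer_cscores(simulate_contact_matrix(truth, cfg, 2), ref)
  other$start <- other$start + 1
  expect_error(compare_profiles(prof, other), "mismatched bin tables")
})
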