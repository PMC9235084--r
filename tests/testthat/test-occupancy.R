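# Peak/compartment assignment and boundary metaplots.

make_profile <- function(labels, bin_size = 25000) {
  bins <- make_bins(setNames(length(labels) * bin_size, "chrT"), bin_size)
  prof <- data.frame(bins, cscore = ifelse(labels == "A", 0.5,
                                           ifelse(labels == "B", -0.5, NA)),
                     label = labels)
  class(prof) <- c("compartment_profile", "data.frame")
  prof
}

test_that("peaks are assigned by midpoint bin and masked bins are excluded", {
  prof <- make_profile(c("A", "A", "B", NA))
  peaks <- data.frame(chrom = "chrT",
                      start = c(1000, 26000, 51000, 76000),
                      end = c(1400, 26400, 51400, 76400))
  occ <- peak_compartment_fraction(peaks, prof)
  expect_equal(occ$n_peaks, 3)
  expect_equal(occ$n_in_A, 2)
  expect_equal(occ$fraction_A, 2 / 3, tolerance = 1e-12)
  expect_equal(occ$n_excluded, 1)

  all_a <- peak_compartment_fraction(peaks[1:2, ], prof)
  expect_equal(all_a$fraction_A, 1)
  expect_error(peak_compartment_fraction(peaks[0, ], prof), "no peaks")
})

test_that("max-overlap assignment picks the bin covering most of the peak", {
  prof <- make_profile(c("A", "B"))
  # 60% of the peak lies in bin 2 (B)
  peak <- data.frame(chrom = "chrT", start = 21000, end = 31000)
  expect_equal(peak_compartment_fraction(peak, prof, assign = "max_overlap")$n_in_A, 0)
  expect_equal(peak_compartment_fraction(peak, prof, assign = "midpoint")$n_in_A, 0)
})

test_that("metaplot reproduces constant, step and averaged-step signals", {
  track <- data.frame(chrom = "chrT", start = 0, end = 1e6, value = 3)
  b <- data.frame(chrom = "chrT", pos = 5e5)
  mp <- boundary_metaplot(track, b, window = 2e5, step = 25000)
  expect_true(all(mp$mean_signal == 3))
  expect_equal(mp$offset, seq(-2e5, 2e5, by = 25000))

  step_track <- data.frame(chrom = "chrT", start = c(0, 5e5), end = c(5e5, 1e6),
                           value = c(0, 1))
  mp2 <- boundary_metaplot(step_track, b, window = 1e5, step = 25000)
  expect_true(all(mp2$mean_signal[mp2$offset < 0] == 0))
  expect_true(all(mp2$mean_signal[mp2$offset >= 0] == 1))

  # two boundaries with steps 0->1 and 0->3 average to a 0->2 step
  two <- data.frame(chrom = c("chrT", "chrU"), pos = c(5e5, 5e5))
  tr2 <- rbind(step_track,
               data.frame(chrom = "chrU", start = c(0, 5e5), end = c(5e5, 1e6),
                          value = c(0, 3)))
  mp3 <- boundary_metaplot(tr2, two, window = 1e5, step = 25000)
  expect_true(all(mp3$mean_signal[mp3$offset < 0] == 0))
  expect_true(all(mp3$mean_signal[mp3$offset >= 0] == 2))

  expect_error(boundary_metaplot(track, b[0, ], window = 1e5), "no boundaries")
})

test_that("boundaries near chromosome ends contribute only covered offsets", {
  track <- data.frame(chrom = "chrT", start = 0, end = 3e5, value = 1)
  b <- data.frame(chrom = "chrT", pos = 50000)
  mp <- boundary_metaplot(track, b, window = 1e5, step = 25000)
  expect_true(all(is.na(mp$mean_signal[mp$offset < -50000])))
  expect_equal(mp$n_boundaries[mp$offset == -75000], 0)
  expect_equal(mp$n_boundaries[mp$offset == 0], 1)
})

test_that("reflecting coordinates and swapping labels reverses the metaplot", {
  set.seed(31)
  L <- 1e6
  bins <- seq(0, L - 25000, by = 25000)
  track <- data.frame(chrom = "chrT", start = bins, end = bins + 25000,
                      value = runif(length(bins)))
  # boundaries at bin midpoints so samples fall strictly inside intervals
  # on both strands of the reflection (interval edges are half-open)
  b <- data.frame(chrom = "chrT", pos = c(3e5, 6e5) + 12500)
  fwd <- boundary_metaplot(track, b, window = 1e5, step = 25000)
  # reflect: x -> L - x; a B->A boundary at p becomes one at L - p
  refl <- data.frame(chrom = "chrT", start = L - track$end, end = L - track$start,
                     value = track$value)
  refl <- refl[order(refl$start), ]
  rb <- data.frame(chrom = "chrT", pos = L - b$pos)
  rev_mp <- boundary_metaplot(refl, rb, window = 1e5, step = 25000)
  expect_equal(rev_mp$mean_signal, rev(fwd$mean_signal), tolerance = 1e-12)
})

test_that("A-enriched synthetic signal rises across B-to-A boundaries", {
  cfg <- small_cfg(seed = 33)
  truth <- simulate_compartment_truth(cfg)
  pk <- simulate_peaks(truth, cfg)
  mp <- boundary_metaplot(pk$signal, truth$boundaries$b2a, window = 2e5,
                          step = cfg$bin_size)
  expect_gt(mean(mp$mean_signal[mp$offset > 0]), mean(mp$mean_signal[mp$offset < 0]))
})
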