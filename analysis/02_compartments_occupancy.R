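#!/usr/bin/env Rscript
# Stage 2: A/B compartment scores from the WT and DKO contact matrices,
# WT-vs-DKO score comparison, segment table with the A:B genomic length
# ratio, peak/compartment occupancy and the B->A boundary metaplot.
# Expects results/dataset from 01_simulate_dataset.R.

library(chromarch)

d <- function(f) file.path("results/dataset", f)
wt <- read_matrix(d("wt_rep1.matrix"), d("wt_rep1.bins.bed"))
dko <- read_matrix(d("dko_rep1.matrix"), d("dko_rep1.bins.bed"))
signal <- read_bedgraph(d("signal.bedgraph"))
peaks <- read_bed(d("peaks.bed"))
truth <- read.table(d("truth_labels.tsv"), header = TRUE, sep = "\t")

prof_wt <- infer_cscores(wt, signal)
prof_dko <- infer_cscores(dko, signal)
write_profile(prof_wt, "results/cscore_wt.bedgraph", "results/segments_wt.bed")
write_profile(prof_dko, "results/cscore_dko.bedgraph", "results/segments_dko.bed")

called <- !is.na(prof_wt$label)
agree <- mean(prof_wt$label[called] == truth$label[called])
cmp <- compare_profiles(prof_wt, prof_dko)
cat(sprintf("Planted-label agreement (WT): %.1f%% of %d called bins\n",
            100 * agree, sum(called)))
cat(sprintf("WT vs DKO C-score Pearson r: %.3f over %d bins; %d switching bins\n",
            cmp$pearson_r, cmp$n_bins_compared, length(cmp$switched_bins)))
cat(sprintf("A:B genomic length ratio: WT %.3f, DKO %.3f\n",
            cmp$ab_ratio_wt, cmp$ab_ratio_dko))

occ <- peak_compartment_fraction(peaks, prof_wt)
cat(sprintf("Peaks in A compartment: %d / %d (%.1f%%), %d unassignable\n",
            occ$n_in_A, occ$n_peaks, 100 * occ$fraction_A, occ$n_excluded))

boundaries <- find_boundaries(prof_wt, "BtoA")
mp <- boundary_metaplot(signal, boundaries, window = 2e5, step = 25000)
write.table(mp, "results/metaplot_b2a.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("Metaplot over %d B->A boundaries: mean signal %.2f (B side) -> %.2f (A side)\n",
            nrow(boundaries),
            mean(mp$mean_signal[mp$offset < 0]), mean(mp$mean_signal[mp$offset > 0])))

summary <- data.frame(
  quantity = c("label_agreement", "wt_dko_pearson_r", "n_switched_bins",
               "ab_ratio_wt", "ab_ratio_dko", "peak_fraction_A"),
  value = c(agree, cmp$pearson_r, length(cmp$switched_bins),
            cmp$ab_ratio_wt, cmp$ab_ratio_dko, occ$fraction_A))
write.table(summary, "results/compartments_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
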