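#!/usr/bin/env Rscript
# Stage 1: generate the complete synthetic study dataset with planted
# ground truth — three replicate Hi-C contact matrices (two "WT", one
# "DKO", all drawn from the same underlying compartment/TAD truth, since
# the question downstream is whether the knockout changes architecture),
# ChIP-seq-style peaks and signal enriched in the A compartment, a
# promoter-capture interaction set with a feature planted at 2-fold
# enrichment on other-ends, and a 16-sample-style WT/DKO ChIP-MS abundance
# design with planted binding partners plus a GO annotation whose enriched
# terms are drawn from those partners.

library(chromarch)

cfg <- sim_config(seed = 1)
out <- simulate_dataset(cfg, "results/dataset")

cat("Synthetic dataset written to results/dataset\n")
cat(sprintf("  genome: %d bins of %d kb across %d chromosomes\n",
            nrow(out$truth$bins), cfg$bin_size / 1000, length(cfg$chrom_sizes)))
cat(sprintf("  planted A fraction: %.3f (target %.3f)\n",
            mean(out$truth$labels == "A"), cfg$a_fraction))
cat(sprintf("  planted B->A boundaries: %d; planted TADs: %d\n",
            nrow(out$truth$boundaries$b2a), nrow(out$truth$tad_intervals)))
cat(sprintf("  interaction calls: %d from %d baits; planted feature fold: %g\n",
            nrow(out$interactions$calls), sum(out$interactions$fragments$is_bait),
            cfg$feature_fold))
cat(sprintf("  proteins: %d per group, %d planted partners\n",
            cfg$n_proteins, length(out$abundance[[1]]$partner_ids)))
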