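#!/usr/bin/env Rscript
# Stage 5: ChIP-MS binding-partner selection (WT1 != 0, WT2 != 0 and a
# WT/DKO average ratio of at least 10), the 10/50/500 threshold sweep in
# both pooling conventions, per-group GO over-representation and the
# four-experiment consensus.
# Expects results/dataset from 01_simulate_dataset.R.

library(chromarch)

d <- function(f) file.path("results/dataset", f)
records <- read_abundance(d("abundance.tsv"))
annotation <- read_gmt(d("annotation.gmt"))
planted_partners <- readLines(d("truth_partners.txt"))
planted_terms <- readLines(d("truth_enriched_terms.txt"))
groups <- unique(records$group)

sweep <- threshold_sweep(records, thresholds = c(10, 50, 500))
write.table(sweep, "results/partner_sweep.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Partner counts by WT/DKO ratio threshold (>= 10, >= 50, > 500):\n")
print(sweep, row.names = FALSE)

universe <- unique(records$protein_id)
ora_by_group <- list()
for (g in groups) {
  part <- select_partners(records[records$group == g, ], threshold = 10)
  ids <- part$protein_id[part$is_partner]
  cat(sprintf("%s: %d partners (%d of %d planted recovered)\n", g, length(ids),
              length(intersect(ids, planted_partners)), length(planted_partners)))
  ora_by_group[[g]] <- ora(ids, universe, annotation)
  write.table(ora_by_group[[g]], sprintf("results/ora_%s.tsv", g), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

cons <- consensus_categories(ora_by_group, required_groups = groups)
write.table(cons$consensus, "results/consensus_terms.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\nGO categories significant in all %d groups: %d (planted enriched terms: %d/%d)\n",
            length(groups), cons$n_consensus,
            sum(planted_terms %in% cons$consensus$term_id), length(planted_terms)))
cat(sprintf("Significant in >= 2 groups: %d; in exactly one group: %d\n",
            cons$n_common, cons$n_unique))
cat("Top consensus categories by combined -log10(q):\n")
print(head(cons$consensus, 5), row.names = FALSE)
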