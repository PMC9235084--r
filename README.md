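# chromarch

Integrative analysis of 3D chromatin architecture around chromatin-bound
proteins, for epigenomics researchers asking the question: *does depleting
a chromatin architectural protein (e.g. a double knockout of the HMGN
nucleosome-binding proteins) reorganize the nucleus, and what does that
protein bind?* The package implements each layer of that analysis over
standard file formats, plus a seeded synthetic-data generator with planted
ground truth so every statistic can be validated end to end without any
external download.

## What it computes

- **A/B compartment scores** from binned Hi-C contact matrices: per
  chromosome, the leading eigenvector of the correlation matrix of
  observed/expected contact columns, rescaled to a per-bin score
  `C ∈ [−1, 1]` and sign-oriented by an active-chromatin reference track
  (`C > 0` = A, `C < 0` = B). Segments, A:B genomic length ratios, B→A
  boundaries, and WT-vs-knockout score comparison with switching-bin
  detection.
- **Peak/compartment occupancy and boundary metaplots**: the fraction of
  ChIP-seq peaks whose midpoint lies in A bins, and the average signal in
  ±200 kb windows across B→A boundaries.
- **Stratum-adjusted correlation (SCC)** between two contact maps:
  per-diagonal Pearson correlations `r_k` combined as
  `SCC = Σ w_k r_k / Σ w_k` with `w_k = n_k · s_k(a) · s_k(b)`, after
  mean-filter smoothing — replicate reproducibility and cross-condition
  similarity without distance-decay inflation.
- **TAD boundaries** via insulation scores
  (`log2` of the cross-boundary contact mean over its chromosome-wide
  mean), domain calling between significant insulation minima, and
  boundary-stability comparison (Jaccard with ±1 bin tolerance).
- **Feature enrichment at promoter-interacting regions (PIRs)**:
  interaction calls filtered at confidence score ≥ 5; observed feature
  overlap of other-end fragments versus 100 random non-bait fragment sets
  matched on distance to the nearest bait; fold enrichment with a 95% CI
  and permutation plus normal-approximation p-values.
- **ChIP-MS binding-partner selection**: a protein is a partner iff
  `WT1 ≠ 0`, `WT2 ≠ 0` and `WT_ave/DKO_ave ≥ 10` (infinite ratios for
  DKO-absent proteins), with a 10/50/500 threshold sweep (500 strict) in
  both pooling conventions; GO over-representation (one-sided Fisher
  exact, Benjamini–Hochberg FDR) and the consensus of categories
  significant in all four experiment groups.

Formats: triplet sparse matrix + bin BED, BED, bedGraph, fragment maps,
interaction TSV, long-format abundance TSV, GMT.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Stage 1
simulates a complete study dataset (three replicate contact matrices from
one planted truth, A-enriched peaks, capture interactions with a feature
planted at 2-fold enrichment, four WT/DKO abundance tables with 50 planted
partners); stages 2–5 analyze it:

```sh
Rscript analysis/01_simulate_dataset.R
Rscript analysis/02_compartments_occupancy.R
```

prints

```
Planted-label agreement (WT): 99.7% of 1400 called bins
WT vs DKO C-score Pearson r: 0.932 over 1400 bins; 4 switching bins
A:B genomic length ratio: WT 0.934, DKO 0.928
Peaks in A compartment: 1564 / 2000 (78.2%), 0 unassignable
Metaplot over 18 B->A boundaries: mean signal 0.97 (B side) -> 2.12 (A side)
```

i.e. the compartment caller recovers the planted labels almost perfectly,
the "knockout" matrix (drawn from the same truth) gives near-identical
scores with only a handful of switching bins, ~78% of peaks sit in the A
compartment (the closed-form expectation for 4:1 placement odds at the
realized A fraction), and the signal steps up sharply across B→A
boundaries. Stage 3 then shows replicate and WT-vs-DKO SCCs are equally
high while a matrix from a different truth separates cleanly, with TAD
boundaries stable at Jaccard ≈ 0.88; stage 4 recovers the planted 2-fold
PIR enrichment (fold 2.01, 95% CI 1.71–2.36) while a null generator run
sits at fold 0.94 with p ≈ 0.5; and stage 5 recovers all 50 planted
partners in every group at every threshold and finds exactly the three
planted GO categories as the four-group consensus.

Outputs land as TSV/BED/bedGraph tables under `results/`. The same
end-to-end run is available programmatically via
`run_pipeline(pipeline_config(seed = 1), "results/pipeline")`, which also
writes md5 provenance so identical configs give bit-identical outputs.

## Layout

```
R/                  implementation (generators, IO, compartments, occupancy,
                    SCC, TADs, PIR enrichment, partners/ORA, pipeline)
analysis/           numbered workflow drivers (simulate → ... → GO consensus)
scripts/acceptance.R  headline-quantity recomputation (JSON out)
tests/testthat/     unit, property and acceptance tests with independent
                    brute-force oracles
vignettes/          methods vignette: models, parameters, design decisions
```
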