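---
title: "Methods: chromatin architecture and chromatin-bound proteome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin architecture and chromatin-bound proteome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

chromarch asks a single integrative question: does depleting a chromatin
architectural protein change 3D genome organization, and what does that
protein bind on chromatin? The package implements the analysis layers that
question needs — A/B compartment scoring, contact-map similarity, TAD
boundary stability, feature enrichment at promoter-interacting fragments,
and ChIP-MS binding-partner selection with GO over-representation — plus a
synthetic-data generator that plants every structure those analyses are
supposed to detect, so the whole pipeline is testable against known truth.

This vignette records the models, the parameters that matter, and the
design decisions taken where the methodology was genuinely open.

## Compartment scores

The genome is binned (25 kb by default) and, per chromosome, the sparse
symmetric contact matrix is processed as follows: bins with zero marginal
count are masked; each entry is divided by the mean count at its diagonal
distance (observed/expected, removing the distance decay); the Pearson
correlation matrix of O/E columns is formed over non-masked bins
(zero-variance columns are masked, not errors); and the eigenvector of the
largest-magnitude eigenvalue, rescaled by its maximum absolute entry, is
the per-bin compartment score in [-1, 1]. The sign is oriented so that
positive scores correlate with a user-supplied "active" reference track —
here, peak density; in real data, peak or gene density — because the A
compartment is the transcriptionally active one. Positive scores are
labeled A, negative B.

Two properties follow directly from the construction and are asserted in
the tests: scores are invariant to global count scaling (the O/E step
divides it out), and on any small matrix the scores agree with an
independent dense eigendecomposition oracle to 1e-8.

This eigenvector-of-O/E-correlation procedure is the package's key
modeling substitution: likelihood-based compartment callers share the same
contract (per-bin score in [-1, 1], sign = compartment) but their internal
optimization is not reproduced here. Users comparing against such tools
should compare labels and score correlations, not raw score magnitudes.
Compartment calling is per chromosome and intrachromosomal only.

A constant matrix leaves the O/E correlation undefined everywhere and is
rejected with an error rather than scored. Chromosomes need at least 20
non-empty bins; with fewer, the eigenvector mostly reflects noise.

`compare_profiles()` reports the Pearson correlation of scores over bins
labeled in both conditions and flags "switching" bins: sign flips whose
absolute score difference is at least `switch_threshold` (default 0.2).
The threshold suppresses sign flips of near-zero scores, which are
abundant and meaningless; 0.2 is an invented default, exposed in the
configuration.

## Compartment boundaries and occupancy

A B-to-A boundary is the start coordinate of the first A bin of a maximal
A run whose nearest labeled left neighbor is B; masked bins are skipped
and never create boundaries themselves. The boundary metaplot samples a
signal track at fixed offsets (default ±200 kb in bin-size steps) around
each boundary, B side on the left, and averages per offset across
boundaries; boundaries closer than the window to a chromosome end
contribute only their covered offsets, and positions with no track
coverage contribute 0 while being tracked in a coverage-fraction column.

Peak/compartment occupancy assigns each peak to the bin containing its
midpoint (a max-overlap mode is available behind a flag; with peaks much
smaller than bins the two agree). Peaks in masked bins are excluded from
numerator and denominator and reported separately — the alternative
(counting them in the denominator) would make the A fraction depend on the
masking rate of the assay rather than on biology.

## Stratum-adjusted correlation (SCC)

Plain Pearson correlation between two Hi-C matrices is dominated by the
distance decay both share. The SCC therefore correlates matrices within
each diagonal distance stratum and combines the per-stratum correlations
with weights `w_k = n_k * s_k(a) * s_k(b)` (pair count times the two
per-stratum standard deviations), after light mean-filter smoothing
(half-window `h = 1` bin by default) and up to a maximum distance (5 Mb by
default). Strata with fewer than 3 pairs or zero variance contribute
nothing. Multi-chromosome SCC is the pair-count-weighted mean of
per-chromosome SCCs. The statistic is symmetric, scale invariant, exactly
1 on self-comparison, and is checked against a brute-force per-diagonal
oracle at 1e-10.

The weight formula reproduces the covariance-weighted combination of the
published SCC without its rank/variance-stabilizing transformation; with
deep counts the two agree closely, and the package makes no significance
claims for SCC values.

## TAD calling

The insulation score of bin `i` is the log2 ratio of the mean count in
the `w × w` square upstream-by-downstream of `i` to the chromosome-wide
mean of that statistic (window 500 kb by default, so `w = 20` bins at
25 kb). Scores are NA within `w` bins of chromosome ends. Boundaries are
local insulation minima whose depth below the nearest flanking maxima
exceeds `min_drop` (0.1 log2 units, invented, exposed). Domains span the
intervals between successive boundaries, with chromosome ends delimiting
the outermost domains; a chromosome with no boundary yields no domains.
Domains outside `[min_size, max_size]` (75 kb - 5 Mb) are dropped.

Nested/hierarchical TADs are deliberately not modeled: the downstream
comparisons rest on counts, size distributions and boundary stability, for
which flat domains suffice. Boundary stability between two TAD sets is a
greedy nearest-match Jaccard with ±1 bin tolerance. Note the resolution
limit: planted domains smaller than the insulation window cannot be
resolved, so recovered counts undercall slightly; the recovery test
therefore compares means over seeds rather than per-seed counts.

## Feature enrichment at promoter-interacting fragments

Interaction calls are filtered at a confidence score of 5 or more
(inclusive), deduplicated per bait/other-end pair keeping the maximum
score. The tested set is the distinct non-bait other-end fragments of cis
calls within 1 Mb of their bait; bait-to-bait calls are excluded because
they have no analog in the non-bait background pool. The observed
statistic is the number of tested fragments overlapping (≥ 1 bp) a
feature interval — fragment-level, not bp-level.

The null draws 100 random sets of non-bait, non-tested fragments with the
same size and the same distance composition as the tested set. The
matching covariate is distance to the nearest bait, for tested and
background fragments alike — baits are the promoters, so this matches the
"distance from promoters" confounder directly, and using a single
covariate for both sides is what makes the matching well defined.
Distances are stratified into 20 log-spaced bins offset by a 5 kb soft
scale (so the finest bins are no narrower than a typical restriction
fragment); bins whose background pool cannot supply the required draw are
merged into their neighbor, and matching fails with an error only when it
is infeasible outright. Random sets exclude tested fragments so the null
stays independent of the signal.

Reported quantities: the null mean and its 2.5/97.5 percentiles, the fold
(observed/expected) with a log-normal 95% CI, and two p-values side by
side. The permutation p (two-sided, +1-smoothed, granularity
`1/(n_rand+1)`) tests the conditional null "the tested set is a random
distance-matched fragment set, given this feature map". The
normal-approximation p targets the generative null and uses the analytic
variance of the observed count (binomial feature assignment plus
finite-pool background-rate noise) — the resampling spread alone
understates that variance, which matters for tails smaller than the
resampling resolution. The fold CI combines observed-count binomial
noise, finite-pool background noise and the Monte-Carlo error of the null
mean on the log scale, the standard construction for a positive ratio.

## ChIP-MS binding partners

A protein is a binding partner in an experiment group iff it is present
in both WT immunoprecipitation replicates (`wt1 != 0` and `wt2 != 0`) and
its replicate-average WT/DKO abundance ratio is at least the threshold
(default 10, inclusive). A protein absent from both DKO replicates has an
infinite ratio and passes any finite threshold — this matches the
knockout-absent reading of specific partners and keeps counts computable
without pseudocounts (a pseudocount mode exists, off by default). The
threshold sweep reports 10/50/500 by default with the 500 cut strict
(`>`), mirroring the convention of quoting a "> 500-fold" tier alongside
inclusive lower tiers, and tallies both conventions: distinct
(protein, group) pairs and distinct proteins, since pooled counts can be
read either way.

Over-representation analysis is the one-sided Fisher exact test
(hypergeometric upper tail) per term after intersecting term members with
the universe, Benjamini-Hochberg FDR across tested terms, ranked by
descending `-log10(q)`. The universe is an explicit required input: the
choice between "all detected proteins" and a whole proteome changes every
p-value, so the package refuses to guess. Consensus categories are terms
with `q < 0.05` in all four experiment groups (two immunoprecipitation
targets × two cell types); terms significant in ≥ 2 groups ("common") and
exactly one ("unique") are tallied alongside, and consensus terms are
ranked by the combined `-log10(q)` summed over groups.

## The synthetic-data generator

The generator is first-class, tested code; its defaults define the study
conditions the tests and the acceptance script run under.

* **Genome**: two chromosomes of 20 and 15 Mb at 25 kb bins (1400 bins).
  Small enough for seconds-scale runs, large enough that each chromosome
  realizes many compartment blocks — on much shorter chromosomes a single
  long geometric block can occasionally dominate, a regime real
  chromosomes of 100+ Mb do not present.
* **Compartments**: alternating A/B blocks with geometric lengths
  (memoryless, so segment sizes vary as in real compartment tracks);
  means are scaled so the stationary A fraction is `a_fraction` (default
  0.444, i.e. an A:B length ratio near 4:5). Boundaries and labels are
  exposed as ground truth.
* **Contacts**: Poisson counts (negative binomial optional) with mean
  proportional to `(d+1)^-alpha * (1 + kappa * s_i * s_j) * tau^[same TAD]`,
  with decay exponent `alpha = 1`, checkerboard strength `kappa = 0.6`,
  TAD boost `tau = 3`, and `depth = 600` expected contacts per bin — the
  deep-coverage regime in which compartment and TAD analyses of real data
  operate. `depth` is defined per bin so that the recovery conditions are
  stated in the same units as the matrices they describe.
* **Peaks**: bins chosen with odds `e = 4` for A bins, giving an expected
  A fraction of `e*nA/(e*nA+nB)` (0.8 in the balanced case); the signal
  track is per-bin peak coverage plus half-normal noise.
* **Capture interactions**: fragments from random cut sites (~6-8 kb),
  random baits, other-ends sampled in cis between 10 kb and 1 Mb from
  their bait with gentle distance decay; every call carries a score ≥ 5.
  The 10 kb minimum mirrors capture pipelines discarding proximal
  re-ligation products and keeps the near-bait background pool populated.
  The feature is planted fragment-level: other-ends carry it with
  probability `phi * base_rate` versus `base_rate` for background, so the
  enrichment fold converges to `phi`.
* **Abundances**: partners (5% of 1000 proteins, identities shared across
  the four groups as real binding partners would be) get lognormal WT
  abundances and DKO = 0; non-partners get WT ≈ DKO with lognormal
  replicate noise (sd 0.3 on the log scale), under which fewer than 1% of
  non-partners exceed a tenfold ratio. Dropout (default 10%) zeroes WT
  cells of non-partners only, so planted truth stays recoverable and the
  filter's WT-presence clause is exercised.
* **GO annotation**: null terms are uniform random member sets; planted
  enriched terms draw members with weight 25 for partners, strong enough
  that even a 10-member planted term is unambiguous.

Determinism: every generator draws from its own RNG stream derived from
`(seed, operation name)`, so outputs are bit-identical under a seed and
adding a generator never shifts another's output.

What the generator does **not** emulate: read-level data (no FASTQ, no
mapping bias, no mappability structure), restriction-site sequence,
interchromosomal contacts, copy-number or GC covariates, correlated
non-partner contaminants in ChIP-MS, and the dependency structure of real
GO DAGs (terms are flat sets). Passing recovery tests therefore
demonstrates correctness of the statistics under their own assumptions,
not robustness to artifacts real data may carry.

## Problem sizes and numerical choices

The test suite and acceptance script run on the default 1400-bin genome
(seconds per contact-matrix analysis), 50-seed windows for
confidence-interval coverage, 200-seed windows for calibration checks,
and 10 000 replicate draws for the block-length convergence check; the
full suite completes in a few minutes. Ties in insulation minima break to
the lower bin; eigenvector sign is left unchanged when the reference
track is constant (a warning-free no-op, since either sign is then
equally defensible); boundary matching in TAD comparison is greedy by
ascending distance with each boundary used once.

## Known limitations

Compartment scores from the eigenvector procedure are comparable across
runs of this package but not numerically interchangeable with
likelihood-based callers; SCC values are reported without significance;
the TAD caller has a hard resolution floor at its window size; the
enrichment null assumes features are exchangeable across fragments within
a distance stratum (fragment-length confounding is not modeled — real
analyses may want length as a second matching covariate); and ORA treats
GO terms as independent flat sets, so parent/child redundancy in real
annotations will produce clusters of related significant terms.
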