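## End-to-end orchestration: simulate -> compartments -> occupancy -> SCC
## -> TADs -> PIR enrichment -> partners -> ORA -> consensus, from a single
## nested config, with provenance digests so a rerun with an identical
## config is bit-identical.

#' Build a pipeline configuration
#'
#' Nested parameter blocks mirroring each module's defaults. Every
#' analysis-stage constant (the score threshold 5, ratio thresholds
#' 10/50/500, alpha 0.05, the 200 kb metaplot window) lives here; the
#' `sim` block is a full [sim_config()].
#'
#' @param seed master seed, forwarded into the simulation config.
#' @param sim a [sim_config()]; its own seed is overridden by `seed`.
#' @param groups ChIP-MS experiment group labels.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = sim_config(seed = seed),
                            groups = c("ES_N1", "ES_N2", "MEF_N1", "MEF_N2")) {
  sim$seed <- seed
  structure(list(
    seed = seed,
    sim = sim,
    groups = groups,
    compartments = list(switch_threshold = 0.2, min_bins = 20),
    occupancy = list(window = 200000),
    scc = list(h = 1, max_dist = 5e6),
    tads = list(window = 5e5, min_drop = 0.1, min_size = 75000,
                max_size = 5e6, tolerance = 1),
    pir = list(score_threshold = 5, n_rand = 100, n_dist_bins = 20, max_dist = 1e6),
    partners = list(thresholds = c(10, 50, 500), alpha = 0.05)
  ), class = "pipeline_config")
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes all stages in dependency order into `outdir`: a complete
#' simulated dataset (written through the format writers and read back, so
#' the IO layer is on the execution path), compartment profiles for WT and
#' DKO with their comparison, peak/compartment occupancy and the boundary
#' metaplot, SCC for replicate / cross-condition / cross-truth matrix
#' pairs, TAD calls and comparison, distance-matched feature enrichment at
#' PIRs, the partner threshold sweep, per-group ORA and the four-group
#' consensus. Every output table is TSV; `provenance.tsv` records an md5
#' digest per output so identical configs give identical digests.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return invisibly, a named list with the summary quantities and paths.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      writeLines(sprintf("FAILED at stage %s: %s", name, conditionMessage(e)),
                 p("FAILED"))
      stopf("pipeline stage %s failed: %s", name, conditionMessage(e))
    })
  }

  data_dir <- p("dataset")
  sim <- stage("simulate", simulate_dataset(config$sim, data_dir, groups = config$groups))

  # read back through the IO layer
  wt1 <- read_matrix(file.path(data_dir, "wt_rep1.matrix"), file.path(data_dir, "wt_rep1.bins.bed"))
  wt2 <- read_matrix(file.path(data_dir, "wt_rep2.matrix"), file.path(data_dir, "wt_rep2.bins.bed"))
  dko <- read_matrix(file.path(data_dir, "dko_rep1.matrix"), file.path(data_dir, "dko_rep1.bins.bed"))
  peaks <- read_bed(file.path(data_dir, "peaks.bed"))
  signal <- read_bedgraph(file.path(data_dir, "signal.bedgraph"))
  fragments <- read_fragments(file.path(data_dir, "fragments.bed"))
  calls <- read_interactions(file.path(data_dir, "interactions.tsv"), fragments)
  feature <- read_bed(file.path(data_dir, "feature.bed"))
  abundance <- read_abundance(file.path(data_dir, "abundance.tsv"))
  annotation <- read_gmt(file.path(data_dir, "annotation.gmt"))

  # compartments
  prof_wt <- stage("compartments", infer_cscores(wt1, signal, min_bins = config$compartments$min_bins))
  prof_dko <- infer_cscores(dko, signal, min_bins = config$compartments$min_bins)
  comp <- compare_profiles(prof_wt, prof_dko, config$compartments$switch_threshold)
  write_profile(prof_wt, p("cscore_wt.bedgraph"), p("segments_wt.bed"))
  write_profile(prof_dko, p("cscore_dko.bedgraph"), p("segments_dko.bed"))
  truth_lab <- sim$truth$labels
  called <- !is.na(prof_wt$label)
  label_agreement <- mean(prof_wt$label[called] == truth_lab[called])

  # occupancy
  occ <- stage("occupancy", peak_compartment_fraction(peaks, prof_wt))
  boundaries <- find_boundaries(prof_wt, "BtoA")
  meta <- boundary_metaplot(signal, boundaries, window = config$occupancy$window,
                            step = config$sim$bin_size)
  write.table(meta, p("metaplot.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  # SCC: replicates, WT vs DKO, and a different underlying truth
  alt_cfg <- config$sim
  alt_cfg$seed <- derive_seed(config$seed, "alt_truth")
  alt_truth <- simulate_compartment_truth(alt_cfg)
  alt_mat <- simulate_contact_matrix(alt_truth, alt_cfg, replicate_seed = 1)
  scc_tab <- data.frame(
    pair = c("wt_rep1-wt_rep2", "wt_rep1-dko_rep1", "wt_rep1-other_truth"),
    scc = c(scc(wt1, wt2, config$scc$h, config$scc$max_dist)$scc,
            scc(wt1, dko, config$scc$h, config$scc$max_dist)$scc,
            scc(wt1, alt_mat, config$scc$h, config$scc$max_dist)$scc))
  write.table(scc_tab, p("scc.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  # TADs
  tads_wt <- stage("tads", call_tads(insulation_profile(wt1, config$tads$window),
                                     config$tads$min_drop, config$tads$min_size,
                                     config$tads$max_size))
  tads_dko <- call_tads(insulation_profile(dko, config$tads$window),
                        config$tads$min_drop, config$tads$min_size, config$tads$max_size)
  tad_cmp <- compare_tads(tads_wt, tads_dko, config$tads$tolerance)
  write.table(tads_wt$tads, p("tads_wt.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  # PIR enrichment
  sig_calls <- filter_significant(calls, config$pir$score_threshold)
  enr <- stage("pir_enrichment",
               feature_enrichment(sig_calls, fragments, feature,
                                  max_dist = config$pir$max_dist,
                                  n_rand = config$pir$n_rand,
                                  n_dist_bins = config$pir$n_dist_bins,
                                  seed = derive_seed(config$seed, "pir_null"),
                                  feature_name = "planted_feature"))
  write.table(enr, p("pir_enrichment.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  # partners + ORA + consensus
  sweep <- stage("partners", threshold_sweep(abundance, config$partners$thresholds))
  write.table(sweep, p("partner_sweep.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  universe <- unique(abundance$protein_id)
  ora_by_group <- lapply(config$groups, function(g) {
    rec <- abundance[abundance$group == g, ]
    part <- select_partners(rec, threshold = 10)
    ora(part$protein_id[part$is_partner], universe, annotation,
        alpha = config$partners$alpha)
  })
  names(ora_by_group) <- config$groups
  cons <- consensus_categories(ora_by_group, alpha = config$partners$alpha,
                               required_groups = config$groups)
  write.table(cons$consensus, p("consensus_terms.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  summary <- data.frame(
    quantity = c("compartment_label_agreement", "ab_ratio_wt", "wt_dko_cscore_r",
                 "n_switched_bins", "peak_fraction_A", "scc_replicates",
                 "scc_wt_dko", "scc_other_truth", "n_tads_wt", "n_tads_dko",
                 "tad_boundary_jaccard", "pir_fold", "n_consensus_terms"),
    value = c(label_agreement, comp$ab_ratio_wt, comp$pearson_r,
              length(comp$switched_bins), occ$fraction_A, scc_tab$scc[1],
              scc_tab$scc[2], scc_tab$scc[3], tad_cmp$n_tads_a, tad_cmp$n_tads_b,
              tad_cmp$boundary_jaccard, enr$fold, cons$n_consensus))
  write.table(summary, p("summary.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  outputs <- sort(setdiff(list.files(outdir, recursive = TRUE), "provenance.tsv"))
  prov <- data.frame(file = outputs,
                     md5 = as.character(tools::md5sum(file.path(outdir, outputs))),
                     seed = config$seed)
  write.table(prov, p("provenance.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(summary = summary, scc = scc_tab, comparison = comp,
                 occupancy = occ, tad_comparison = tad_cmp, enrichment = enr,
                 sweep = sweep, consensus = cons, outdir = outdir))
}
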