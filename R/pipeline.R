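# End-to-end orchestration: simulate (optional) -> per-channel preprocess
# -> MLE merge -> sex-chromosome drop -> differential -> annotation ->
# Fisher enrichment -> directional permutation tests, with every stage's
# tables written before the next begins and a run manifest at the end.

#' Run the full analysis pipeline
#'
#' Executes the ordered stages on a simulated (or supplied) study and
#' writes each stage's output tables under `out_dir` as TSV, plus a run
#' manifest (seed, config snapshot, stage timings, file digests). Rerunning
#' with the same config and seed produces byte-identical tables, and
#' stage-by-stage invocation through the exported stage functions gives
#' the same outputs.
#'
#' @param sim A study list as returned by [simulate_tab_study()]; when
#'   `NULL`, one is simulated from `sim_cfg` and `seed`.
#' @param out_dir Output directory, created if needed; `NULL` skips all
#'   file output.
#' @param config An [hmc_config()].
#' @param sim_cfg An [sim_config()] used when `sim` is `NULL`.
#' @param seed Integer seed for simulation and permutation stages.
#' @return A list of stage results: `qc`, `profile` (autosomal
#'   `modification_profile`), `correlations`, `differential`, `split`,
#'   `annotation`, `enrichment`, `permutation`, `manifest_path`.
#' @export
run_pipeline <- function(sim = NULL, out_dir = NULL, config = hmc_config(),
                         sim_cfg = sim_config(), seed = config$rng_seed) {
  t0 <- proc.time()[["elapsed"]]
  stages <- list(); written <- character()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    stages[[length(stages) + 1L]] <<- tibble(stage = stage,
                                             elapsed_s = round(t1 - t0, 3))
    t0 <<- t1
  }
  emit <- function(x, name) {
    if (is.null(out_dir)) return(invisible())
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(out_dir, name)
    if (is.matrix(x)) write_tsv_matrix(x, path)
    else readr::write_tsv(x, path, progress = FALSE)
    written <<- c(written, path)
  }

  if (is.null(sim)) sim <- simulate_tab_study(sim_cfg, seed, config)
  tick("simulate")

  # per-channel QC (union removal) and preprocessing
  qc <- combine_and_remove(sim$observed$bs, sim$observed$tab,
                           threshold = config$detection_p_threshold,
                           max_fraction = config$detection_sample_fraction)
  emit(dplyr::select(qc$qc_report, "channel", "n_failed"), "qc_report.tsv")
  tick("qc")
  bs <- preprocess_channel(qc$bs, sim$observed$controls_bs, config)
  tab <- preprocess_channel(qc$tab, sim$observed$controls_tab, config)
  tick("preprocess")

  # MLE merge, then restrict to the autosomal analyzed set
  profile <- build_modification_profile(bs, tab, sim$observed$sample_sheet, config)
  manifest_auto <- drop_sex_chromosomes(
    sim$genome$manifest[sim$genome$manifest$probe_id %in% rownames(profile$beta_5hmc), ])
  profile <- subset_profile(profile, manifest_auto$probe_id)
  emit(profile$beta_5mc, "beta_5mc.tsv")
  emit(profile$beta_5hmc, "beta_5hmc.tsv")
  tick("estimate")

  correlations <- per_cpg_correlation(profile)
  emit(summarize_correlations(correlations), "correlation_summary.tsv")
  tick("correlation")

  differential <- paired_test(profile, moderation = config$moderation,
                              alpha = config$bonferroni_alpha)
  emit(tibble::as_tibble(differential), "differential.tsv")
  split <- direction_split(differential)
  emit(split$counts, "direction_counts.tsv")
  tick("differential")

  annotation <- annotate_probes(manifest_auto, sim$genome$genes,
                                sim$genome$exons, cgi = sim$genome$cgi,
                                histone = sim$genome$histone, config = config)
  tick("annotate")

  selected <- differential$probe_id[differential$significant]
  enrichment <- if (length(selected) > 0)
    enrichment_table(selected, annotation)
  else tibble()
  emit(enrichment, "enrichment.tsv")
  tick("enrich")

  permutation <- directional_subsets(split, annotation, sim$gene_sets,
                                     n_perm = config$n_permutations,
                                     seed = seed, rule = config$permutation_rule)
  emit(dplyr::select(permutation, -"result"), "permutation.tsv")
  tick("permtest")

  manifest_path <- NULL
  if (!is.null(out_dir))
    manifest_path <- write_run_manifest(out_dir, config,
                                        stages = bind_rows(stages),
                                        files = written)
  list(sim = sim, qc = qc, profile = profile, correlations = correlations,
       differential = differential, split = split, annotation = annotation,
       enrichment = enrichment, permutation = permutation,
       manifest_path = manifest_path)
}

#' Summary tables for reporting
#'
#' Derives the figure-style numeric tables from pipeline results:
#' cumulative modification-level proportions (overall and per feature
#' class), the per-CpG correlation summary, the M-value matrix of the
#' selected loci (heatmap input), the enrichment odds-ratio table and the
#' permutation null histograms. Numbers only; plotting is a thin layer on
#' top (see `plot_` functions).
#'
#' @param results List from [run_pipeline()].
#' @param config An [hmc_config()] (M-value clamp).
#' @return List: `cumulative`, `correlation_summary`, `mvalues`
#'   (selected-loci M-value matrix, units as columns), `enrichment`,
#'   `permutation_null` (tibble of null counts per run).
#' @export
report_tables <- function(results, config = hmc_config()) {
  if (is.null(results$profile)) hmc_abort("missing upstream output: estimate stage")
  fc <- exclusive_feature_class(results$annotation,
                                precedence = config$feature_precedence)
  cumulative <- summarize_distributions(results$profile, feature_class = fc)
  selected <- results$differential$probe_id[results$differential$significant]
  mvalues <- beta_to_mvalue(
    results$profile$beta_5hmc[selected, , drop = FALSE], eps = config$mvalue_eps)
  null_tbl <- if (nrow(results$permutation) > 0)
    results$permutation %>%
      mutate(null = lapply(.data$result, function(r) r$null_counts)) %>%
      dplyr::select("direction", "gene_set", "null") %>%
      tidyr::unnest_longer("null", values_to = "null_count")
  else tibble()
  list(cumulative = cumulative,
       correlation_summary = summarize_correlations(results$correlations),
       mvalues = mvalues,
       enrichment = results$enrichment,
       permutation_null = null_tbl)
}
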