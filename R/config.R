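# Run configuration and run manifest.

#' Analysis configuration
#'
#' Collects the tunable parameters of the pipeline. Defaults mirror common
#' array practice: probes failing detection p > 1e-6 in more than 5% of
#' samples are dropped; Bonferroni family-wise alpha 0.05; 100,000
#' permutations for gene-set empirical p-values; promoter window TSS
#' -1500/+500 bp (strand-aware); beta offset 100.
#'
#' @param detection_p_threshold Detection p above this counts as a failure.
#' @param detection_sample_fraction Probe fails when the failing-sample
#'   fraction strictly exceeds this.
#' @param bonferroni_alpha Family-wise significance cutoff on adjusted p.
#' @param n_permutations Iterations for permutation gene-set tests.
#' @param rng_seed Integer seed recorded in the run manifest.
#' @param promoter_upstream,promoter_downstream Promoter window around the
#'   TSS, in bp, strand-aware.
#' @param beta_offset Stabilizing constant in beta = M / (M + U + offset).
#' @param mvalue_eps Clamp for beta before the logit (M-value) transform.
#' @param moderation Use empirical-Bayes variance moderation in the paired
#'   test (`TRUE`, default) or the plain paired t-test.
#' @param permutation_rule `"strict_greater"` (default) or
#'   `"greater_or_equal"` for the empirical-p counting rule.
#' @param quantile_pooled Quantile-normalize BS and TAB samples pooled
#'   together (`TRUE`) rather than per channel (default `FALSE`).
#' @param mle_w_bs,mle_w_tab Pseudo-depth weights for the two channels in
#'   the constrained MLE.
#' @param feature_precedence Exclusive feature-class precedence, highest first.
#' @param ... Further fields stored as-is (e.g. paths).
#' @return A named list of class `hmc_config`.
#' @export
hmc_config <- function(detection_p_threshold = 1e-6,
                       detection_sample_fraction = 0.05,
                       bonferroni_alpha = 0.05,
                       n_permutations = 100000L,
                       rng_seed = 1L,
                       promoter_upstream = 1500L,
                       promoter_downstream = 500L,
                       beta_offset = 100,
                       mvalue_eps = 1e-6,
                       moderation = TRUE,
                       permutation_rule = c("strict_greater", "greater_or_equal"),
                       quantile_pooled = FALSE,
                       mle_w_bs = 1,
                       mle_w_tab = 1,
                       feature_precedence = c("promoter", "exon", "intron",
                                              "gene_body", "intergenic"),
                       ...) {
  cfg <- list(
    detection_p_threshold = detection_p_threshold,
    detection_sample_fraction = detection_sample_fraction,
    bonferroni_alpha = bonferroni_alpha,
    n_permutations = as.integer(n_permutations),
    rng_seed = as.integer(rng_seed),
    promoter_upstream = as.integer(promoter_upstream),
    promoter_downstream = as.integer(promoter_downstream),
    beta_offset = beta_offset,
    mvalue_eps = mvalue_eps,
    moderation = isTRUE(moderation),
    permutation_rule = match.arg(permutation_rule),
    quantile_pooled = isTRUE(quantile_pooled),
    mle_w_bs = mle_w_bs, mle_w_tab = mle_w_tab,
    feature_precedence = feature_precedence,
    ...)
  stopifnot(
    cfg$detection_p_threshold > 0, cfg$detection_p_threshold < 1,
    cfg$detection_sample_fraction > 0, cfg$detection_sample_fraction < 1,
    cfg$bonferroni_alpha > 0, cfg$bonferroni_alpha <= 1,
    cfg$n_permutations >= 1, cfg$beta_offset >= 0,
    cfg$mvalue_eps > 0, cfg$mvalue_eps < 0.5,
    cfg$mle_w_bs > 0, cfg$mle_w_tab > 0)
  structure(cfg, class = c("hmc_config", "list"))
}

#' Read / write a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` comments allowed. Values are parsed
#' as numbers or logicals where possible; comma-separated values become
#' vectors. Unknown keys are passed through to [hmc_config()].
#'
#' @param path File path.
#' @return For `read_config`, an `hmc_config`; for `write_config`, `path`.
#' @export
read_config <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- lengths(kv) != 3
  if (any(bad)) hmc_abort(sprintf("config line not 'key = value': '%s'", lines[bad][1]))
  vals <- lapply(kv, function(m) {
    v <- strsplit(trimws(m[3]), "\\s*,\\s*")[[1]]
    parsed <- suppressWarnings(as.numeric(v))
    if (!anyNA(parsed)) parsed
    else if (all(v %in% c("TRUE", "FALSE", "true", "false"))) toupper(v) == "TRUE"
    else v
  })
  names(vals) <- vapply(kv, `[[`, character(1), 2)
  do.call(hmc_config, vals)
}

#' @rdname read_config
#' @param config An `hmc_config`.
#' @export
write_config <- function(config, path) {
  fmt <- function(v) paste(vapply(v, function(x) format(x, scientific = FALSE, trim = TRUE),
                                  character(1)), collapse = ", ")
  keep <- vapply(config, function(v) is.atomic(v) && length(v) >= 1, logical(1))
  readr::write_lines(paste(names(config)[keep], "=",
                           vapply(config[keep], fmt, character(1))), path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, seed, decisions in effect, stage
#' order with timings, and md5 digests of the files a stage read and wrote,
#' as JSON next to the stage outputs.
#'
#' @param dir Output directory (one manifest per output directory).
#' @param config The `hmc_config` in effect.
#' @param stages Tibble or data.frame with columns `stage`, `elapsed_s`.
#' @param files Character vector of file paths to digest.
#' @return The manifest path, invisibly.
#' @export
write_run_manifest <- function(dir, config, stages = NULL, files = character()) {
  files <- files[file.exists(files)]
  manifest <- list(
    package = "tabhmc",
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$rng_seed,
    decisions = list(moderation = config$moderation,
                     permutation_rule = config$permutation_rule,
                     promoter_window = c(-config$promoter_upstream,
                                         config$promoter_downstream),
                     beta_offset = config$beta_offset,
                     quantile_pooled = config$quantile_pooled),
    config = unclass(config)[vapply(config, is.atomic, logical(1))],
    stages = stages,
    digests = as.list(tools::md5sum(files)))
  path <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
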