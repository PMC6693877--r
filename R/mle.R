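# Constrained maximum-likelihood resolution of (5mC, 5hmC) from the paired
# BS and TAB channels, plus distribution / correlation summaries.
#
# Channel semantics: bisulfite alone protects both modifications, so the BS
# channel reads p_bs = p_5mC + p_5hmC; TAB chemistry glucosylates 5hmC and
# oxidizes 5mC, so the TAB channel reads p_tab = p_5hmC. The MLE maximizes
# the product of two binomial likelihoods with pseudo-counts beta * w under
# p_5mC >= 0, p_5hmC >= 0, p_5mC + p_5hmC <= 1.

#' Maximum-likelihood (5mC, 5hmC) estimates from paired channel betas
#'
#' Interior solution (when `beta_tab <= beta_bs`): `p_5hmC = beta_tab`,
#' `p_5mC = beta_bs - beta_tab`. When the measurement noise puts
#' `beta_tab > beta_bs`, the constrained optimum lies on the boundary
#' `p_5mC = 0` with `p_5hmC` the pseudo-depth-weighted average
#' `(beta_bs * w_bs + beta_tab * w_tab) / (w_bs + w_tab)`.
#'
#' @param beta_bs,beta_tab Numeric vectors (or matrices of equal shape) of
#'   channel beta values in `[0, 1]`.
#' @param w_bs,w_tab Positive pseudo-depth weights; array betas carry no
#'   read depth, so both default to 1.
#' @return A list with components `beta_5mc` and `beta_5hmc`, the same
#'   shape as the inputs, satisfying the simplex constraints.
#' @export
estimate_modifications <- function(beta_bs, beta_tab, w_bs = 1, w_tab = 1) {
  if (any(!is.finite(beta_bs)) || any(!is.finite(beta_tab)))
    hmc_abort("non-finite channel beta values")
  if (any(beta_bs < 0 | beta_bs > 1) || any(beta_tab < 0 | beta_tab > 1))
    hmc_abort("channel beta values must lie in [0, 1]")
  if (any(w_bs <= 0) || any(w_tab <= 0)) hmc_abort("weights must be positive")
  boundary <- beta_tab > beta_bs
  hmc <- ifelse(boundary,
                (beta_bs * w_bs + beta_tab * w_tab) / (w_bs + w_tab),
                beta_tab)
  mc <- ifelse(boundary, 0, beta_bs - beta_tab)
  if (is.matrix(beta_bs)) {
    hmc <- matrix(hmc, nrow(beta_bs), dimnames = dimnames(beta_bs))
    mc <- matrix(mc, nrow(beta_bs), dimnames = dimnames(beta_bs))
  }
  list(beta_5mc = mc, beta_5hmc = hmc)
}

#' Build a modification profile from preprocessed channels
#'
#' Pairs each unit (subject x tissue) with its own BS and TAB samples and
#' runs [estimate_modifications()] per probe, giving per-unit 5mC and 5hmC
#' beta matrices on a shared probe x unit grid. Unit columns are named
#' `subject_id.tissue`.
#'
#' @param bs,tab Preprocessed [channel_matrix()] objects carrying `beta`.
#' @param sample_sheet Sample sheet tibble (see [read_sample_sheet()]).
#' @param config An [hmc_config()] (supplies the pseudo-depth weights).
#' @return An object of class `modification_profile`: list with `beta_5mc`,
#'   `beta_5hmc` (probe x unit matrices) and `units` (tibble of unit
#'   metadata in column order).
#' @export
build_modification_profile <- function(bs, tab, sample_sheet,
                                       config = hmc_config()) {
  sheet <- validate_sample_sheet(sample_sheet)
  if (!identical(probe_ids(bs), probe_ids(tab)))
    hmc_abort("BS and TAB channels must share an identical probe axis")
  units <- sheet %>%
    distinct(.data$subject_id, .data$tissue) %>%
    arrange(.data$subject_id, .data$tissue) %>%
    mutate(unit = paste(.data$subject_id, .data$tissue, sep = "."))
  lookup <- function(assay) {
    m <- sheet[sheet$assay == assay, ]
    ids <- m$sample_id[match(paste(units$subject_id, units$tissue),
                             paste(m$subject_id, m$tissue))]
    if (anyNA(ids)) hmc_abort(sprintf("missing %s sample for some unit", assay))
    ids
  }
  bmat <- bs$beta[, lookup("BS"), drop = FALSE]
  tmat <- tab$beta[, lookup("TAB"), drop = FALSE]
  est <- estimate_modifications(bmat, tmat,
                                w_bs = config$mle_w_bs, w_tab = config$mle_w_tab)
  colnames(est$beta_5mc) <- colnames(est$beta_5hmc) <- units$unit
  structure(list(beta_5mc = est$beta_5mc, beta_5hmc = est$beta_5hmc,
                 units = units),
            class = "modification_profile")
}

#' @export
print.modification_profile <- function(x, ...) {
  cat(sprintf("<modification_profile> %d probes x %d units (%d subjects)\n",
              nrow(x$beta_5hmc), ncol(x$beta_5hmc),
              length(unique(x$units$subject_id))))
  invisible(x)
}

#' @export
dim.modification_profile <- function(x) dim(x$beta_5hmc)

#' Tidy a modification profile into a long tibble
#'
#' @param x A `modification_profile`.
#' @param ... Unused.
#' @return Tibble with probe_id, subject_id, tissue, beta_5mc, beta_5hmc.
#' @export
tidy.modification_profile <- function(x, ...) {
  tibble(
    probe_id = rep(rownames(x$beta_5hmc), times = ncol(x$beta_5hmc)),
    subject_id = rep(x$units$subject_id, each = nrow(x$beta_5hmc)),
    tissue = rep(x$units$tissue, each = nrow(x$beta_5hmc)),
    beta_5mc = as.vector(x$beta_5mc),
    beta_5hmc = as.vector(x$beta_5hmc))
}

#' Subset a modification profile to a set of probes
#'
#' @param x A `modification_profile`.
#' @param probes Probe ids to keep (order preserved from `x`).
#' @return A `modification_profile`.
#' @export
subset_profile <- function(x, probes) {
  keep <- intersect(rownames(x$beta_5hmc), probes)
  structure(list(beta_5mc = x$beta_5mc[keep, , drop = FALSE],
                 beta_5hmc = x$beta_5hmc[keep, , drop = FALSE],
                 units = x$units),
            class = "modification_profile")
}

#' Per-CpG correlation between 5mC and 5hmC across units
#'
#' Pearson correlation of the two modification levels across units, one
#' coefficient per probe. Probes where either vector is constant get
#' `NA` and `degenerate = TRUE`; they are excluded from summary fractions.
#'
#' @param profile A `modification_profile` (>= 3 units).
#' @return Tibble with `probe_id`, `r`, `degenerate`.
#' @export
per_cpg_correlation <- function(profile) {
  mc <- profile$beta_5mc; hmc <- profile$beta_5hmc
  if (!identical(dimnames(mc), dimnames(hmc)))
    hmc_abort("5mC and 5hmC matrices must share axes")
  if (ncol(mc) < 3) hmc_abort("need >= 3 units per probe for a correlation")
  cx <- mc - rowMeans(mc); cy <- hmc - rowMeans(hmc)
  sx <- rowSums(cx^2); sy <- rowSums(cy^2)
  degenerate <- sx == 0 | sy == 0
  r <- rowSums(cx * cy) / sqrt(sx * sy)
  r[degenerate] <- NA_real_
  tibble(probe_id = rownames(mc), r = unname(pmin(pmax(r, -1), 1)),
         degenerate = unname(degenerate))
}

#' Summarize per-CpG correlations
#'
#' @param correlations Tibble from [per_cpg_correlation()].
#' @return One-row tibble: number of probes, number degenerate, fraction
#'   with r < 0 and r > 0 (among non-degenerate), mean and median r.
#' @export
summarize_correlations <- function(correlations) {
  ok <- correlations$r[!correlations$degenerate]
  tibble(n_probes = nrow(correlations),
         n_degenerate = sum(correlations$degenerate),
         frac_negative = mean(ok < 0),
         frac_positive = mean(ok > 0),
         mean_r = mean(ok), median_r = median(ok))
}

#' Cumulative modification-level distributions
#'
#' Cumulative proportion of probe x unit beta values at or below each grid
#' point, per modification type, optionally stratified by tissue and by an
#' exclusive genomic feature class.
#'
#' @param profile A `modification_profile`.
#' @param grid Beta grid points, default `seq(0, 1, by = 0.01)`.
#' @param feature_class Optional named character vector (probe_id ->
#'   exclusive class, see [exclusive_feature_class()]).
#' @param by_tissue Also stratify by tissue (default `TRUE`).
#' @return Tibble with columns `modification`, `tissue`, `feature_class`,
#'   `beta`, `cumulative_proportion`.
#' @export
summarize_distributions <- function(profile, grid = seq(0, 1, by = 0.01),
                                    feature_class = NULL, by_tissue = TRUE) {
  long <- tidy(profile) %>%
    tidyr::pivot_longer(c("beta_5mc", "beta_5hmc"),
                        names_to = "modification", values_to = "beta_value") %>%
    mutate(modification = if_else(.data$modification == "beta_5mc", "5mC", "5hmC"))
  if (!is.null(feature_class))
    long$feature_class <- unname(feature_class[long$probe_id])
  else long$feature_class <- "all"
  if (!by_tissue) long$tissue <- "all"
  ecdf_tbl <- function(v) {
    tibble(beta = grid, cumulative_proportion = vapply(
      grid, function(g) mean(v <= g), numeric(1)))
  }
  long %>%
    group_by(.data$modification, .data$tissue, .data$feature_class) %>%
    dplyr::reframe(ecdf_tbl(.data$beta_value))
}

#' Locate modes of a beta-value sample by histogram smoothing
#'
#' Bins values on `[0, 1]`, lightly smooths the counts, and reports local
#' maxima above a mass floor. Used to verify the bimodal 5mC / unimodal
#' low 5hmC shapes.
#'
#' @param values Beta values.
#' @param n_bins Histogram bins, default 50.
#' @param min_mass Minimum fraction of values in a bin for it to count as
#'   a mode, default 0.005.
#' @return Tibble with `mode` (bin midpoint) and `mass` (smoothed density
#'   fraction), sorted by location.
#' @export
find_beta_modes <- function(values, n_bins = 50, min_mass = 0.005) {
  breaks <- seq(0, 1, length.out = n_bins + 1)
  h <- graphics::hist(pmin(pmax(values, 0), 1), breaks = breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  sm <- stats::filter(p, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- p[is.na(sm)]
  sm <- as.numeric(sm)
  left <- c(-Inf, sm[-length(sm)]); right <- c(sm[-1], -Inf)
  is_mode <- sm > left & sm >= right & sm >= min_mass
  # collapse flat-topped runs to their first bin
  tibble(mode = h$mids[is_mode], mass = sm[is_mode]) %>% arrange(.data$mode)
}
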