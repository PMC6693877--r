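# One-sided Fisher enrichment of probe sets over annotation labels, and
# permutation-based gene-set enrichment with empirical p-values.

#' One-sided Fisher enrichment of a probe set over a label
#'
#' Builds the 2x2 table of probe set vs background-complement (background
#' minus set) against carrying the label, with a = in-set probes with the
#' label, b = in-set without, c = complement with, d = complement without.
#' The odds ratio is (a*d)/(b*c) (+Inf when b*c = 0 and a*d > 0) and the
#' one-sided enrichment p is the hypergeometric upper tail P(X >= a);
#' depletion is read from the lower tail and reported when OR < 1.
#'
#' @param probe_set Character vector of probe ids (subset of `background`).
#' @param background Character vector: the analyzed probe universe.
#' @param labelled Character vector: background probes carrying the label.
#' @param label Label name recorded in the output.
#' @return One-row tibble: `label`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `p_enrichment` (upper tail), `p_depletion` (lower tail), `p_one_sided`
#'   (tail matching the direction of the odds ratio).
#' @export
fisher_enrichment <- function(probe_set, background, labelled, label = "label") {
  if (length(probe_set) == 0) hmc_abort("empty probe set")
  if (!all(probe_set %in% background))
    hmc_abort("`probe_set` must be a subset of `background`")
  labelled <- intersect(labelled, background)
  a <- sum(probe_set %in% labelled)
  b <- length(probe_set) - a
  c_ <- length(labelled) - a
  d <- length(background) - length(probe_set) - c_
  or <- if (b * c_ == 0) {
    if (a * d > 0) Inf else NaN
  } else (a * d) / (b * c_)
  n_set <- a + b; n_lab <- a + c_; n_tot <- a + b + c_ + d
  p_up <- phyper(a - 1, n_lab, n_tot - n_lab, n_set, lower.tail = FALSE)
  p_lo <- phyper(a, n_lab, n_tot - n_lab, n_set, lower.tail = TRUE)
  tibble(label = label, a = a, b = b, c = c_, d = d, odds_ratio = or,
         p_enrichment = p_up, p_depletion = p_lo,
         p_one_sided = if (is.finite(or) && or < 1) p_lo else p_up)
}

#' Fisher enrichment across all annotation labels
#'
#' Runs [fisher_enrichment()] for each label (feature classes, CGI,
#' histone marks) present in the annotation of the background.
#'
#' @param probe_set Probe ids (e.g. the differential loci).
#' @param annotation An `annotation_table` covering the background.
#' @param labels Labels to test (default: all labels observed).
#' @return Tibble with one row per label, sorted by `p_one_sided`.
#' @export
enrichment_table <- function(probe_set, annotation, labels = NULL) {
  background <- annotation$probe_id
  long <- tibble(probe_id = rep(annotation$probe_id, lengths(annotation$labels)),
                 label = unlist(annotation$labels))
  if (is.null(labels)) labels <- sort(unique(long$label))
  purrr::map_dfr(labels, function(l) {
    fisher_enrichment(probe_set, background,
                      labelled = unique(long$probe_id[long$label == l]),
                      label = l)
  }) %>% arrange(.data$p_one_sided)
}

#' Map a probe set to its host genes
#'
#' @param probe_set Probe ids.
#' @param annotation An `annotation_table`.
#' @return Sorted character vector: the union of host genes over the
#'   probes (deduplicated; intergenic probes contribute nothing).
#' @export
map_set_to_genes <- function(probe_set, annotation) {
  idx <- match(probe_set, annotation$probe_id)
  sort(unique(unlist(annotation$hosts[idx[!is.na(idx)]])))
}

#' Permutation gene-set enrichment with an empirical p-value
#'
#' Observed statistic: the number of distinct target genes hit by the probe
#' set. Null: each iteration draws the same number of probes uniformly
#' without replacement from the background, maps them to host genes, and
#' counts distinct genes in the target set. The empirical p is the
#' proportion of null counts strictly larger than the observed count
#' (`"strict_greater"`, default), or at least as large
#' (`"greater_or_equal"`); the `(b + 1) / (n + 1)` small-sample correction
#' is available via `add_one = TRUE`.
#'
#' @param probe_set Probe ids (k = `length(probe_set)` is the draw size).
#' @param annotation An `annotation_table`; its probes are the background.
#' @param target_genes Nonempty character vector of target genes.
#' @param n_perm Number of iterations, default 100,000.
#' @param seed Integer seed; the full null is reproducible given it.
#' @param rule Counting rule (see above).
#' @param add_one Apply the (b + 1)/(n + 1) correction, default `FALSE`.
#' @return A `permutation_result`: list with `observed` (gene-hit count),
#'   `n_perm`, `null_counts` (integer vector), `empirical_p`, `seed`,
#'   `rule`, `k`, `target_size`.
#' @export
permutation_enrichment <- function(probe_set, annotation, target_genes,
                                   n_perm = 100000L, seed = 1L,
                                   rule = c("strict_greater", "greater_or_equal"),
                                   add_one = FALSE) {
  rule <- match.arg(rule)
  if (length(target_genes) == 0) hmc_abort("`target_genes` must be nonempty")
  n_bg <- nrow(annotation)
  k <- length(probe_set)
  if (k > n_bg) hmc_abort("probe set larger than background")
  target_genes <- unique(target_genes)
  # CSR layout of probe -> target-gene indices, so each iteration touches
  # only the sampled probes that host a target gene
  tg_per_probe <- lapply(annotation$hosts, function(h) {
    m <- match(h, target_genes)
    m[!is.na(m)]
  })
  counts <- lengths(tg_per_probe)
  flat <- unlist(tg_per_probe)
  offsets <- c(0L, cumsum(counts))
  observed <- length(unique(unlist(
    tg_per_probe[match(probe_set, annotation$probe_id)])))
  null_counts <- integer(n_perm)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  nonzero <- counts > 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n_bg, k)
    idx <- idx[nonzero[idx]]
    if (length(idx) == 0L) next
    genes <- flat[sequence(counts[idx], from = offsets[idx] + 1L)]
    null_counts[i] <- length(unique(genes))
  }
  b <- switch(rule,
              strict_greater = sum(null_counts > observed),
              greater_or_equal = sum(null_counts >= observed))
  p <- if (add_one) (b + 1) / (n_perm + 1) else b / n_perm
  structure(list(observed = observed, n_perm = n_perm,
                 null_counts = null_counts, empirical_p = p, seed = seed,
                 rule = rule, add_one = add_one, k = k,
                 target_size = length(target_genes)),
            class = "permutation_result")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("<permutation_result> observed %d target genes ",
                     "(k = %d probes); empirical p = %.4g ",
                     "(%s, %d permutations, seed %d)\n"),
              x$observed, x$k, x$empirical_p, x$rule, x$n_perm, x$seed))
  invisible(x)
}

#' @export
tidy.permutation_result <- function(x, ...) {
  tibble(null_count = x$null_counts)
}

#' @export
glance.permutation_result <- function(x, ...) {
  tibble(observed = x$observed, empirical_p = x$empirical_p,
         n_perm = x$n_perm, rule = x$rule, seed = x$seed, k = x$k,
         target_size = x$target_size,
         null_mean = mean(x$null_counts), null_sd = sd(x$null_counts))
}

#' Directional permutation runs over gene-set categories
#'
#' Runs [permutation_enrichment()] for each combination of change
#' direction (from [direction_split()]) and gene-set category: the
#' lower-in-tumor and higher-in-tumor loci are each tested against the
#' unfavorable-prognostic, favorable-prognostic and elevated gene sets.
#' Empty probe subsets are skipped with a notice.
#'
#' @param split Result of [direction_split()].
#' @param annotation An `annotation_table`.
#' @param gene_sets Tibble from [read_gene_sets()].
#' @param logrank_threshold Strict log-rank p cutoff for prognostic genes.
#' @param n_perm,seed,rule Passed to [permutation_enrichment()]; seeds for
#'   the individual runs are derived from `seed` deterministically.
#' @return Tibble with `direction`, `gene_set`, `k`, `observed`,
#'   `empirical_p`, and a `result` list-column of `permutation_result`s.
#' @export
directional_subsets <- function(split, annotation, gene_sets,
                                logrank_threshold = 1e-3,
                                n_perm = 100000L, seed = 1L,
                                rule = "strict_greater") {
  sets <- list(
    unfavorable = filter_prognostic(gene_sets, logrank_threshold, "unfavorable")$gene,
    favorable = filter_prognostic(gene_sets, logrank_threshold, "favorable")$gene,
    elevated = gene_sets$gene[gene_sets$category == "elevated"])
  subsets <- list(lower_in_tumor = split$lower_in_tumor,
                  higher_in_tumor = split$higher_in_tumor)
  rows <- list()
  run_id <- 0L
  for (dir in names(subsets)) {
    for (gs in names(sets)) {
      run_id <- run_id + 1L
      if (length(subsets[[dir]]) == 0 || length(sets[[gs]]) == 0) {
        inform(sprintf("skipping %s x %s: empty subset or gene set", dir, gs))
        next
      }
      res <- permutation_enrichment(subsets[[dir]], annotation, sets[[gs]],
                                    n_perm = n_perm,
                                    seed = (seed + 101L * run_id) %% .Machine$integer.max,
                                    rule = rule)
      rows[[length(rows) + 1L]] <- tibble(
        direction = dir, gene_set = gs, k = res$k, observed = res$observed,
        empirical_p = res$empirical_p, result = list(res))
    }
  }
  if (length(rows) == 0) return(tibble(direction = character(),
                                       gene_set = character(), k = integer(),
                                       observed = integer(),
                                       empirical_p = double(),
                                       result = list()))
  bind_rows(rows)
}
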