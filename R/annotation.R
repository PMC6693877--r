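# Mapping probes to genomic features: CpG islands, promoter / exon /
# intron / gene body / intergenic classes, histone gapped peaks, and host
# genes. All internal coordinates are 0-based half-open; 1-based manifest
# positions are converted exactly once, here.

#' Build a queryable interval index
#'
#' Wraps a tibble of 0-based half-open intervals (`chrom`, `start`, `end`,
#' `label`) as a `GRanges` for overlap queries. Point queries return the
#' same result as a linear scan.
#'
#' @param features Tibble of intervals (see [read_bed()]).
#' @return A `GRanges` with a `label` metadata column.
#' @export
build_interval_index <- function(features) {
  if (any(features$start >= features$end)) hmc_abort("intervals need start < end")
  GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    label = features$label)
}

# Probe manifest (1-based pos) -> width-1 GRanges; the one conversion point.
probes_to_granges <- function(manifest) {
  GenomicRanges::GRanges(
    seqnames = manifest$chrom,
    ranges = IRanges::IRanges(start = manifest$pos, width = 1L),
    probe_id = manifest$probe_id)
}

#' Point-overlap query of probes against an interval index
#'
#' @param manifest Probe manifest tibble (`probe_id`, `chrom`, `pos` 1-based).
#' @param index A `GRanges` from [build_interval_index()].
#' @return Tibble with one row per (probe, covering interval): `probe_id`,
#'   `label`.
#' @export
query_interval_index <- function(manifest, index) {
  gr <- probes_to_granges(manifest)
  # probes may live on chromosomes the feature set does not mention; that
  # is handled (and warned about) at the annotate_probes level
  hits <- withCallingHandlers(
    GenomicRanges::findOverlaps(gr, index, ignore.strand = TRUE),
    warning = function(w) {
      if (grepl("sequence levels in common", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  tibble(probe_id = gr$probe_id[S4Vectors::queryHits(hits)],
         label = index$label[S4Vectors::subjectHits(hits)])
}

#' Derive promoter, gene-body, exon and intron intervals from gene models
#'
#' The promoter is the strand-aware window TSS - upstream .. TSS +
#' downstream; the gene body spans TSS..TES; introns are the gene body
#' minus the union of exons across transcripts, computed per gene.
#'
#' @param genes Tibble with `gene`, `chrom`, `strand` (`+`/`-`), `start`,
#'   `end` (0-based half-open transcript span).
#' @param exons Tibble with `gene`, `chrom`, `start`, `end` (0-based
#'   half-open exon intervals).
#' @param upstream,downstream Promoter window in bp around the TSS.
#' @return A list of interval tibbles: `promoter`, `gene_body`, `exon`,
#'   `intron`, each with `chrom`, `start`, `end`, `label` (= gene symbol).
#' @export
derive_gene_features <- function(genes, exons, upstream = 1500L,
                                 downstream = 500L) {
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  prom_start <- ifelse(genes$strand == "+", tss - upstream, tss - downstream + 1L)
  prom_end <- ifelse(genes$strand == "+", tss + downstream, tss + upstream + 1L)
  promoter <- tibble(chrom = genes$chrom,
                     start = pmax(0L, as.integer(prom_start)),
                     end = as.integer(prom_end), label = genes$gene)
  gene_body <- tibble(chrom = genes$chrom, start = genes$start,
                      end = genes$end, label = genes$gene)
  exon_tbl <- tibble(chrom = exons$chrom, start = exons$start,
                     end = exons$end, label = exons$gene)
  # introns: per gene, gene body minus union of exons
  exon_gr <- GenomicRanges::reduce(GenomicRanges::split(
    build_interval_index(exon_tbl), exon_tbl$label))
  body_gr <- GenomicRanges::split(build_interval_index(gene_body), gene_body$label)
  intron_gr <- GenomicRanges::psetdiff(
    unlist(body_gr[names(exon_gr)]), exon_gr)
  intron_flat <- unlist(intron_gr)
  intron <- tibble(chrom = as.character(GenomicRanges::seqnames(intron_flat)),
                   start = GenomicRanges::start(intron_flat) - 1L,
                   end = GenomicRanges::end(intron_flat),
                   label = rep(names(intron_gr), lengths(intron_gr)))
  genes_without_exons <- setdiff(genes$gene, unique(exons$gene))
  if (length(genes_without_exons) > 0)
    intron <- bind_rows(intron,
                        gene_body[gene_body$label %in% genes_without_exons, ])
  list(promoter = promoter, gene_body = gene_body, exon = exon_tbl,
       intron = arrange(intron, .data$chrom, .data$start))
}

#' Annotate probes with genomic features, histone marks and host genes
#'
#' Multi-label annotation: a probe can be in the promoter of one gene and
#' the intron of another; every covering gene contributes to the host set.
#' A probe with no host gene (and not in any promoter) is intergenic.
#' Histone gapped-peak labels are orthogonal, as is CGI membership.
#'
#' @param manifest Probe manifest tibble.
#' @param genes,exons Gene models for [derive_gene_features()].
#' @param cgi Tibble of CpG-island intervals (or `NULL`).
#' @param histone Tibble of histone-peak intervals with mark names in
#'   `label` (or `NULL`).
#' @param config An [hmc_config()] (promoter window).
#' @return An `annotation_table`: tibble with `probe_id`, `labels`
#'   (list-column of feature labels), `hosts` (list-column of host genes),
#'   `cgi` (logical), `intergenic` (logical).
#' @export
annotate_probes <- function(manifest, genes, exons, cgi = NULL, histone = NULL,
                            config = hmc_config()) {
  known_chroms <- unique(c(genes$chrom, if (!is.null(cgi)) cgi$chrom,
                           if (!is.null(histone)) histone$chrom))
  missing_chrom <- setdiff(unique(manifest$chrom), known_chroms)
  if (length(missing_chrom) > 0)
    warn(paste0("probe chromosome(s) absent from all annotations: ",
                paste(missing_chrom, collapse = ", ")))
  feats <- derive_gene_features(genes, exons,
                                upstream = config$promoter_upstream,
                                downstream = config$promoter_downstream)
  hit <- function(tbl, what) {
    if (is.null(tbl) || nrow(tbl) == 0)
      return(tibble(probe_id = character(), label = character(), class = character()))
    query_interval_index(manifest, build_interval_index(tbl)) %>%
      mutate(class = what)
  }
  gene_hits <- bind_rows(hit(feats$promoter, "promoter"),
                         hit(feats$exon, "exon"),
                         hit(feats$intron, "intron"),
                         hit(feats$gene_body, "gene_body"))
  cgi_hits <- hit(cgi, "CGI")
  histone_hits <- if (is.null(histone) || nrow(histone) == 0)
    tibble(probe_id = character(), label = character())
  else query_interval_index(manifest, build_interval_index(histone))

  split_on <- function(ids, values) {
    out <- split(values, factor(ids, levels = manifest$probe_id))
    lapply(out, unique)
  }
  class_labels <- split_on(gene_hits$probe_id, gene_hits$class)
  # hosts: genes whose body or promoter window covers the probe
  hosts <- split_on(gene_hits$probe_id, gene_hits$label)
  mark_labels <- split_on(histone_hits$probe_id, histone_hits$label)
  cgi_flag <- manifest$probe_id %in% cgi_hits$probe_id

  intergenic <- lengths(hosts) == 0
  labels <- mapply(function(cl, mk, ig, cg) {
    base <- if (ig) "intergenic" else cl
    if (cg) base <- c(base, "CGI")
    c(base, mk)
  }, class_labels, mark_labels, intergenic, cgi_flag, SIMPLIFY = FALSE)

  out <- tibble(probe_id = manifest$probe_id,
                labels = unname(labels),
                hosts = unname(lapply(hosts, function(h) sort(h))),
                cgi = cgi_flag,
                intergenic = unname(intergenic))
  structure(out, class = c("annotation_table", class(out)))
}

#' Collapse multi-label annotation to one exclusive feature class per probe
#'
#' Deterministic single class by precedence (default promoter > exon >
#' intron > gene_body > intergenic); CGI membership is tracked orthogonally
#' and never competes.
#'
#' @param annotation An `annotation_table` from [annotate_probes()].
#' @param precedence Character vector, highest precedence first; must end
#'   in `"intergenic"`.
#' @return Named character vector probe_id -> class.
#' @export
exclusive_feature_class <- function(annotation,
                                    precedence = c("promoter", "exon", "intron",
                                                   "gene_body", "intergenic")) {
  cls <- vapply(annotation$labels, function(l) {
    found <- precedence[precedence %in% l]
    if (length(found) == 0) "intergenic" else found[1]
  }, character(1))
  setNames(cls, annotation$probe_id)
}

#' Remove probes on sex chromosomes
#'
#' Handles both the `chrX`/`chrY` and bare `X`/`Y` naming dialects.
#'
#' @param manifest Probe manifest tibble.
#' @return The manifest without sex-chromosome probes; the number removed
#'   is reported via `inform()`.
#' @export
drop_sex_chromosomes <- function(manifest) {
  sex <- manifest$chrom %in% c("chrX", "chrY", "X", "Y")
  if (any(sex))
    inform(sprintf("removed %d sex-chromosome probe(s)", sum(sex)))
  manifest[!sex, , drop = FALSE]
}
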