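# BED / gappedPeak interval input and gene-set tables.

#' Read intervals from BED or gappedPeak files
#'
#' Accepts BED3+ (chrom, start, end, optional name, optional score) and
#' 15-column gappedPeak. Coordinates are kept 0-based half-open. gappedPeak
#' blocks are flattened to the outer chromStart..chromEnd span: colocalization
#' downstream is against the whole peak region, not its blocks.
#'
#' @param path File path; `#`, `track` and `browser` lines are skipped.
#' @param label Optional label applied to every interval (e.g. a histone
#'   mark name); otherwise column 4 (or `"."`) is used.
#' @return A tibble with columns `chrom`, `start`, `end`, `label`, `score`.
#' @export
read_bed <- function(path, label = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  label = character(), score = double()))
  parts <- strsplit(lines, "[ \t]+")
  nfield <- lengths(parts)
  if (any(nfield < 3))
    hmc_abort(sprintf("'%s': fewer than 3 fields at line %d", path, lineno[which(nfield < 3)[1]]))
  chrom <- vapply(parts, `[[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 3)))
  if (anyNA(start) || anyNA(end))
    hmc_abort(sprintf("'%s': non-integer coordinate at line %d", path,
                      lineno[which(is.na(start) | is.na(end))[1]]))
  bad <- start >= end
  if (any(bad))
    hmc_abort(sprintf("'%s': start >= end at line %d", path, lineno[which(bad)[1]]))
  name <- ifelse(nfield >= 4, vapply(parts, function(p) if (length(p) >= 4) p[[4]] else ".", character(1)), ".")
  score <- suppressWarnings(as.numeric(
    vapply(parts, function(p) if (length(p) >= 5) p[[5]] else NA_character_, character(1))))
  tibble(chrom = chrom, start = start, end = end,
         label = if (is.null(label)) name else label, score = score)
}

#' Write intervals as BED
#'
#' @param x Tibble with `chrom`, `start`, `end` and optionally `label`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  out <- tibble(chrom = x$chrom, start = x$start, end = x$end,
                name = if ("label" %in% names(x)) x$label else ".",
                score = if ("score" %in% names(x)) ifelse(is.na(x$score), 0, x$score) else 0)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a gene-set table
#'
#' Tab-delimited with columns `gene`, `category` (`prognostic` or
#' `elevated`), `direction` (`favorable`, `unfavorable`, `none`) and
#' `logrank_p` (blank/NA when absent, e.g. for `elevated` entries).
#'
#' @param path File path.
#' @return A tibble, one row per gene-set entry.
#' @export
read_gene_sets <- function(path) {
  gs <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(logrank_p = "d", .default = "c"))
  validate_gene_sets(gs)
}

validate_gene_sets <- function(gs) {
  need <- c("gene", "category", "direction", "logrank_p")
  if (!all(need %in% names(gs)))
    hmc_abort(paste0("gene-set table needs columns: ", paste(need, collapse = ", ")))
  gs <- tibble::as_tibble(gs)[need]
  bad <- setdiff(unique(gs$category), c("prognostic", "elevated"))
  if (length(bad) > 0)
    hmc_abort(paste0("unknown gene-set category: ", paste(bad, collapse = ", ")))
  bad <- setdiff(unique(gs$direction), c("favorable", "unfavorable", "none"))
  if (length(bad) > 0)
    hmc_abort(paste0("unknown direction token: ", paste(bad, collapse = ", ")))
  p <- gs$logrank_p
  if (any(!is.na(p) & (p <= 0 | p > 1)))
    hmc_abort("logrank_p must lie in (0, 1] when present")
  gs
}

#' Filter prognostic gene-set entries by log-rank p
#'
#' Keeps `prognostic` entries whose log-rank p is strictly below
#' `threshold` (survival screens conventionally use p < 0.001).
#'
#' @param gene_sets Tibble from [read_gene_sets()].
#' @param threshold Strict upper bound on the log-rank p.
#' @param direction Optional: keep only `"favorable"` or `"unfavorable"` entries.
#' @return The filtered tibble.
#' @export
filter_prognostic <- function(gene_sets, threshold = 1e-3, direction = NULL) {
  out <- dplyr::filter(gene_sets, .data$category == "prognostic",
                       !is.na(.data$logrank_p), .data$logrank_p < threshold)
  if (!is.null(direction)) out <- dplyr::filter(out, .data$direction == .env$direction)
  out
}
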