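# Channel matrices, sample sheets and probe manifests.
#
# A channel matrix holds one assay channel (BS or TAB) as probes x samples,
# either as a signal pair (methylated-state and unmethylated-state
# intensities) or as beta values, with an optional parallel detection-p
# matrix. Coordinates in probe manifests are 1-based (array-manifest
# convention) and are converted to 0-based half-open exactly once, at read
# time, by the annotation layer.

#' Construct a channel matrix
#'
#' Container for one assay channel (`"BS"` or `"TAB"`): probes x samples
#' measurements, either a signal pair (`m_signal`, `u_signal`) or a `beta`
#' matrix, plus an optional `detection_p` matrix on the same axes.
#'
#' @param assay `"BS"` or `"TAB"`.
#' @param m_signal,u_signal Non-negative intensity matrices (probes x
#'   samples) for the methylated-state and unmethylated-state signals, or
#'   `NULL` when `beta` is supplied.
#' @param beta Matrix of beta values in `[0, 1]`, or `NULL`.
#' @param detection_p Optional matrix of detection p-values in `[0, 1]`.
#' @return An object of class `channel_matrix`.
#' @export
channel_matrix <- function(assay, m_signal = NULL, u_signal = NULL,
                           beta = NULL, detection_p = NULL) {
  assay <- match.arg(assay, c("BS", "TAB"))
  has_signal <- !is.null(m_signal) || !is.null(u_signal)
  if (has_signal && is.null(m_signal) != is.null(u_signal))
    hmc_abort("supply both `m_signal` and `u_signal`, or neither")
  if (!has_signal && is.null(beta))
    hmc_abort("supply either a signal pair or a `beta` matrix")
  ref <- if (has_signal) m_signal else beta
  check_axes <- function(m, name) {
    if (is.null(m)) return(invisible())
    if (!is.matrix(m) || !is.numeric(m))
      hmc_abort(sprintf("`%s` must be a numeric matrix", name))
    if (is.null(rownames(m)) || is.null(colnames(m)))
      hmc_abort(sprintf("`%s` must carry probe rownames and sample colnames", name))
    if (!identical(dim(m), dim(ref)) || !identical(dimnames(m), dimnames(ref)))
      hmc_abort(sprintf("`%s` axes disagree with the other matrices", name))
    if (anyNA(m)) hmc_abort(sprintf("`%s` contains missing values; QC removes probes instead", name))
    invisible()
  }
  check_axes(ref, if (has_signal) "m_signal" else "beta")
  check_axes(u_signal, "u_signal"); check_axes(beta, "beta")
  check_axes(detection_p, "detection_p")
  if (anyDuplicated(rownames(ref)))
    hmc_abort(paste0("duplicate probe ids: ",
                     paste(unique(rownames(ref)[duplicated(rownames(ref))]), collapse = ", ")))
  if (has_signal && (any(m_signal < 0) || any(u_signal < 0)))
    hmc_abort("signal intensities must be non-negative")
  if (!is.null(beta) && (any(beta < 0) || any(beta > 1)))
    hmc_abort("`beta` values must lie in [0, 1]")
  if (!is.null(detection_p) && (any(detection_p < 0) || any(detection_p > 1)))
    hmc_abort("`detection_p` values must lie in [0, 1]")
  structure(
    list(assay = assay, m_signal = m_signal, u_signal = u_signal,
         beta = beta, detection_p = detection_p),
    class = "channel_matrix")
}

#' @export
print.channel_matrix <- function(x, ...) {
  d <- dim(if (!is.null(x$beta)) x$beta else x$m_signal)
  cat(sprintf("<channel_matrix> assay=%s  %d probes x %d samples  [%s%s]\n",
              x$assay, d[1], d[2],
              if (!is.null(x$m_signal)) "signals" else "beta",
              if (!is.null(x$detection_p)) " + detection_p" else ""))
  invisible(x)
}

#' @export
dim.channel_matrix <- function(x) dim(if (!is.null(x$beta)) x$beta else x$m_signal)

#' Probe and sample ids of a channel matrix
#'
#' @param x A [channel_matrix()].
#' @return Character vector of row (probe) or column (sample) labels.
#' @export
probe_ids <- function(x) rownames(if (!is.null(x$beta)) x$beta else x$m_signal)

#' @rdname probe_ids
#' @export
sample_ids <- function(x) colnames(if (!is.null(x$beta)) x$beta else x$m_signal)

#' Tidy a channel matrix into a long tibble
#'
#' @param x A [channel_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per probe x sample cell.
#' @export
tidy.channel_matrix <- function(x, ...) {
  mats <- list(m_signal = x$m_signal, u_signal = x$u_signal,
               beta = x$beta, detection_p = x$detection_p)
  mats <- mats[!vapply(mats, is.null, logical(1))]
  out <- tibble(
    probe_id = rep(rownames(mats[[1]]), times = ncol(mats[[1]])),
    sample_id = rep(colnames(mats[[1]]), each = nrow(mats[[1]])),
    assay = x$assay)
  for (nm in names(mats)) out[[nm]] <- as.vector(mats[[nm]])
  out
}

read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) hmc_abort(sprintf("'%s': expected probe column plus sample columns", path))
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    hmc_abort(sprintf("'%s': duplicate probe rows: %s", path,
                      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  vals <- df[-1]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    col <- names(vals)[which(bad)[1]]
    row <- which(is.na(suppressWarnings(as.numeric(vals[[col]]))))[1]
    hmc_abort(sprintf("'%s': non-numeric cell at probe row %s, column '%s'",
                      path, ifelse(is.na(row), "?", row), col))
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

write_tsv_matrix <- function(m, path) {
  # 17 significant digits guarantee bitwise double round-trip
  chars <- formatC(m, digits = 17, format = "g")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("probe_id", colnames(m)), collapse = "\t"), con)
  writeLines(paste(rownames(m), apply(chars, 1, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

#' Read a channel matrix from tab-delimited files
#'
#' Expects a probe-by-sample table with a header row of sample ids and a
#' leading probe-id column; an optional parallel detection-p table on the
#' same axes. When a sample sheet is supplied, the file's sample columns are
#' validated against the sheet's entries for that assay.
#'
#' @param path Path to the value matrix (signal or beta, per `layout`).
#' @param assay `"BS"` or `"TAB"`.
#' @param layout `"beta"` (default) or `"signal"`; for `"signal"`,
#'   `u_path` must name the unmethylated-signal matrix.
#' @param u_path Path of the unmethylated-signal matrix when `layout = "signal"`.
#' @param detection_p_path Optional path of the detection-p matrix.
#' @param sample_sheet Optional tibble from [read_sample_sheet()].
#' @return A [channel_matrix()].
#' @export
read_channel_matrix <- function(path, assay, layout = c("beta", "signal"),
                                u_path = NULL, detection_p_path = NULL,
                                sample_sheet = NULL) {
  layout <- match.arg(layout)
  m <- read_tsv_matrix(path)
  dp <- if (!is.null(detection_p_path)) read_tsv_matrix(detection_p_path)
  cm <- if (layout == "beta") {
    channel_matrix(assay, beta = m, detection_p = dp)
  } else {
    if (is.null(u_path)) hmc_abort("`u_path` required for layout = \"signal\"")
    channel_matrix(assay, m_signal = m, u_signal = read_tsv_matrix(u_path),
                   detection_p = dp)
  }
  if (!is.null(sample_sheet)) {
    expected <- sample_sheet$sample_id[sample_sheet$assay == assay]
    got <- sample_ids(cm)
    if (!setequal(expected, got)) {
      off <- c(setdiff(expected, got), setdiff(got, expected))
      hmc_abort(sprintf("sample axis disagrees with sample sheet for assay %s: %s",
                        assay, paste(off, collapse = ", ")))
    }
  }
  cm
}

#' Write a channel matrix to tab-delimited files
#'
#' @param x A [channel_matrix()].
#' @param path Path for the value matrix (beta, or methylated signal).
#' @param u_path,detection_p_path Paths for the unmethylated-signal and
#'   detection-p matrices when present in `x`.
#' @return `path`, invisibly.
#' @export
write_channel_matrix <- function(x, path, u_path = NULL, detection_p_path = NULL) {
  if (!is.null(x$beta)) write_tsv_matrix(x$beta, path)
  else write_tsv_matrix(x$m_signal, path)
  if (!is.null(x$u_signal)) {
    if (is.null(u_path)) hmc_abort("`u_path` required: channel carries a signal pair")
    write_tsv_matrix(x$u_signal, u_path)
  }
  if (!is.null(x$detection_p) && !is.null(detection_p_path))
    write_tsv_matrix(x$detection_p, detection_p_path)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-delimited with columns `sample_id`, `subject_id`, `tissue`
#' (`tumor`/`adjacent`) and `assay` (`BS`/`TAB`). In a complete paired
#' design every subject appears with both tissues and both assays.
#'
#' @param path File path.
#' @param require_complete Check the complete 2 x 2 design per subject.
#' @return A tibble, one row per sample.
#' @export
read_sample_sheet <- function(path, require_complete = TRUE) {
  sheet <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  validate_sample_sheet(sheet, require_complete)
}

#' @rdname read_sample_sheet
#' @param sheet A sample-sheet data frame to validate in place.
#' @export
validate_sample_sheet <- function(sheet, require_complete = TRUE) {
  need <- c("sample_id", "subject_id", "tissue", "assay")
  if (!all(need %in% names(sheet)))
    hmc_abort(paste0("sample sheet needs columns: ", paste(need, collapse = ", ")))
  sheet <- tibble::as_tibble(sheet)[need]
  if (!all(sheet$tissue %in% c("tumor", "adjacent")))
    hmc_abort("tissue must be 'tumor' or 'adjacent'")
  if (!all(sheet$assay %in% c("BS", "TAB")))
    hmc_abort("assay must be 'BS' or 'TAB'")
  key <- paste(sheet$subject_id, sheet$tissue, sheet$assay)
  if (anyDuplicated(key))
    hmc_abort(paste0("duplicate (subject, tissue, assay): ",
                     paste(unique(key[duplicated(key)]), collapse = "; ")))
  if (require_complete) {
    counts <- dplyr::count(sheet, .data$subject_id)
    bad <- counts$subject_id[counts$n != 4L]
    if (length(bad) > 0)
      hmc_abort(paste0("incomplete design for subject(s): ", paste(bad, collapse = ", ")))
  }
  sheet
}

#' Read a probe manifest
#'
#' Tab-delimited with columns `probe_id`, `chrom`, `pos` (1-based CpG
#' coordinate) and `strand` (`+`, `-`, or `*` for unknown).
#'
#' @param path File path.
#' @return A tibble with one row per probe.
#' @export
read_probe_manifest <- function(path) {
  man <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(pos = "i", .default = "c"))
  validate_probe_manifest(man)
}

#' @rdname read_probe_manifest
#' @param man A probe-manifest data frame to validate in place.
#' @export
validate_probe_manifest <- function(man) {
  need <- c("probe_id", "chrom", "pos", "strand")
  if (!all(need %in% names(man)))
    hmc_abort(paste0("probe manifest needs columns: ", paste(need, collapse = ", ")))
  man <- tibble::as_tibble(man)[need]
  if (anyDuplicated(man$probe_id))
    hmc_abort(paste0("duplicate probe ids in manifest: ",
                     paste(unique(man$probe_id[duplicated(man$probe_id)]), collapse = ", ")))
  if (any(man$pos < 1L)) hmc_abort("manifest positions are 1-based; pos must be >= 1")
  if (any(!nzchar(man$chrom))) hmc_abort("empty chromosome name in manifest")
  man$strand[!man$strand %in% c("+", "-")] <- "*"
  man
}
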