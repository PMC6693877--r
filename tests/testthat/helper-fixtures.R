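# Small in-code fixtures shared across test files.

# Build a modification_profile directly from 5hmC (and optional 5mC)
# matrices whose columns alternate adjacent/tumor per subject.
make_profile <- function(beta_5hmc, beta_5mc = NULL) {
  np <- ncol(beta_5hmc) / 2
  units <- tibble::tibble(
    subject_id = rep(sprintf("S%02d", seq_len(np)), each = 2),
    tissue = rep(c("adjacent", "tumor"), np))
  units$unit <- paste(units$subject_id, units$tissue, sep = ".")
  colnames(beta_5hmc) <- units$unit
  if (is.null(rownames(beta_5hmc)))
    rownames(beta_5hmc) <- sprintf("p%04d", seq_len(nrow(beta_5hmc)))
  if (is.null(beta_5mc)) beta_5mc <- beta_5hmc * 0
  dimnames(beta_5mc) <- dimnames(beta_5hmc)
  structure(list(beta_5mc = beta_5mc, beta_5hmc = beta_5hmc, units = units),
            class = "modification_profile")
}

# A tiny hand-built genome: two genes on chr1 (one per strand), one on
# chr2, a CpG island, and two histone peaks. Coordinates 0-based half-open.
tiny_genome <- function() {
  genes <- tibble::tibble(
    gene = c("GA", "GB", "GC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    start = c(1000L, 5000L, 2000L),
    end = c(3000L, 8000L, 4000L))
  exons <- tibble::tibble(
    gene = c("GA", "GA", "GB", "GC"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(1000L, 2500L, 5000L, 2000L),
    end = c(1500L, 3000L, 6000L, 4000L))
  cgi <- tibble::tibble(chrom = "chr1", start = 900L, end = 1200L, label = "CGI")
  histone <- tibble::tibble(
    chrom = c("chr1", "chr2"), start = c(2400L, 100L),
    end = c(2600L, 300L), label = c("H3K4me1", "H3K9me3"))
  list(genes = genes, exons = exons, cgi = cgi, histone = histone)
}

# The 6-probe enumeration fixture for permutation tests: hosts
# (g1),(g1),(g2),(g3),(g4),(g5); target {g1, g2}.
six_probe_annotation <- function() {
  tibble::tibble(
    probe_id = paste0("p", 1:6),
    labels = replicate(6, "gene_body", simplify = FALSE),
    hosts = list("g1", "g1", "g2", "g3", "g4", "g5"),
    cgi = FALSE, intergenic = FALSE)
}

tiny_sim_config <- function(...) {
  defaults <- list(n_probes = 600L, n_subjects = 5L, n_genes = 50L,
                   n_controls = 60L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
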