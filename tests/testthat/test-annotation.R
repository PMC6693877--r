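test_that("point queries respect 1-based probe vs 0-based half-open interval conventions", {
  features <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L,
                             label = "H3K4me1")
  idx <- build_interval_index(features)
  man <- tibble::tibble(probe_id = c("in150", "in101", "out201", "in200"),
                        chrom = "chr1", pos = c(150L, 101L, 201L, 200L),
                        strand = "+")
  hits <- query_interval_index(man, idx)
  # 1-based 150 -> 0-based 149 in [100, 200); 201 -> 200 excluded
  expect_setequal(hits$probe_id, c("in150", "in101", "in200"))
  expect_error(build_interval_index(
    tibble::tibble(chrom = "chr1", start = 5L, end = 5L, label = "x")),
    "start < end")
})

test_that("the interval index equals a linear scan on random fixtures", {
  set.seed(41)
  for (rep in 1:3) {
    n_iv <- 300; n_probes <- 800
    features <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), n_iv, replace = TRUE),
      start = sample.int(5000, n_iv, replace = TRUE) - 1L,
      label = sample(letters[1:4], n_iv, replace = TRUE))
    features$end <- features$start + sample.int(200, n_iv, replace = TRUE)
    man <- tibble::tibble(
      probe_id = sprintf("p%04d", seq_len(n_probes)),
      chrom = sample(c("chr1", "chr2"), n_probes, replace = TRUE),
      pos = sample.int(5500, n_probes, replace = TRUE), strand = "+")
    got <- query_interval_index(man, build_interval_index(features)) %>%
      dplyr::arrange(probe_id, label)
    want <- linear_scan_overlap(man, features) %>%
      dplyr::arrange(probe_id, label)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("gene features derive strand-aware promoters and exon-complement introns", {
  g <- tiny_genome()
  f <- derive_gene_features(g$genes, g$exons, upstream = 1500L, downstream = 500L)
  # + strand gene GA: TSS at 1000 (0-based), promoter [-500, +500] around it
  pa <- f$promoter[f$promoter$label == "GA", ]
  expect_equal(pa$start, 0L)      # 1000 - 1500 clamped at 0
  expect_equal(pa$end, 1500L)     # 1000 + 500
  # - strand gene GB: TSS at end - 1 = 7999
  pb <- f$promoter[f$promoter$label == "GB", ]
  expect_equal(pb$start, 7999L - 500L + 1L)
  expect_equal(pb$end, 7999L + 1500L + 1L)
  # introns of GA: body [1000,3000) minus exons [1000,1500)+[2500,3000)
  ia <- f$intron[f$intron$label == "GA", ]
  expect_equal(ia$start, 1500L)
  expect_equal(ia$end, 2500L)
  # GC is single-exon covering its whole body: no intron rows
  expect_false("GC" %in% f$intron$label)
})

test_that("probe annotation is multi-label with consistent host genes", {
  g <- tiny_genome()
  man <- tibble::tibble(
    probe_id = c("pExon", "pIntron", "pInterHist", "pProm", "pCGI"),
    chrom = c("chr1", "chr1", "chr2", "chr1", "chr1"),
    pos = c(1200L, 2000L, 150L, 7601L, 950L),
    strand = "+")
  ann <- annotate_probes(man, g$genes, g$exons, cgi = g$cgi, histone = g$histone)
  lab <- function(p) ann$labels[[match(p, ann$probe_id)]]
  host <- function(p) ann$hosts[[match(p, ann$probe_id)]]

  expect_true(all(c("exon", "gene_body") %in% lab("pExon")))
  expect_equal(host("pExon"), "GA")
  expect_true(all(c("intron", "gene_body") %in% lab("pIntron")))
  # probe in an intergenic histone peak only
  expect_setequal(lab("pInterHist"), c("intergenic", "H3K9me3"))
  expect_equal(host("pInterHist"), character(0))
  # pProm at 1-based 7601 (0-based 7600): inside GB's minus-strand promoter
  # window [7500, 9501) and inside GB's body -> hosted by GB
  expect_true("promoter" %in% lab("pProm"))
  expect_true("GB" %in% host("pProm"))
  # CGI is orthogonal and co-occurs with genic labels
  expect_true("CGI" %in% lab("pCGI"))
  expect_true(ann$cgi[ann$probe_id == "pCGI"])

  # invariants: intergenic <=> empty hosts; intron => gene_body
  expect_equal(ann$intergenic, lengths(ann$hosts) == 0)
  has_intron <- vapply(ann$labels, function(l) "intron" %in% l, logical(1))
  has_body <- vapply(ann$labels, function(l) "gene_body" %in% l, logical(1))
  expect_true(all(!has_intron | has_body))
})

test_that("a probe overlapping two genes is hosted by both", {
  genes <- tibble::tibble(gene = c("A", "B"), chrom = "chr1",
                          strand = c("+", "+"),
                          start = c(1000L, 2400L), end = c(2000L, 6000L))
  exons <- tibble::tibble(gene = c("A", "B"), chrom = "chr1",
                          start = c(1000L, 5000L), end = c(2000L, 6000L))
  # probe at 0-based 2450: in promoter window of nothing... it is inside
  # B's body upstream of its first exon (intron) and within 500 bp
  # downstream of A's TES? Use A promoter at 1000: probe 2450 is in B intron
  # and in no part of A; second probe 950 is in A's promoter and upstream of B
  man <- tibble::tibble(probe_id = c("pBoth", "pPromA"), chrom = "chr1",
                        pos = c(2451L, 700L), strand = "+")
  ann <- annotate_probes(man, genes, exons)
  expect_true(all(c("intron") %in% ann$labels[[1]]))
  expect_equal(ann$hosts[[1]], "B")
  expect_true("promoter" %in% ann$labels[[2]])
  expect_equal(ann$hosts[[2]], "A")

  # overlapping promoter-of-A / intron-of-B probe
  man2 <- tibble::tibble(probe_id = "pOverlap", chrom = "chr1",
                         pos = c(2500L), strand = "+")
  genes2 <- genes; genes2$start[1] <- 2600L; genes2$end[1] <- 4000L
  exons2 <- exons; exons2$start[1] <- 2600L; exons2$end[1] <- 4000L
  ann2 <- annotate_probes(man2, genes2, exons2)
  expect_true(all(c("promoter", "intron") %in% ann2$labels[[1]]))
  expect_setequal(ann2$hosts[[1]], c("A", "B"))
})

test_that("unknown probe chromosomes warn and fall through to intergenic", {
  g <- tiny_genome()
  man <- tibble::tibble(probe_id = "pX", chrom = "chr9", pos = 100L, strand = "+")
  expect_warning(ann <- annotate_probes(man, g$genes, g$exons), "chr9")
  expect_equal(ann$labels[[1]], "intergenic")
})

test_that("exclusive feature classes follow the configured precedence", {
  ann <- tibble::tibble(
    probe_id = c("a", "b", "c"),
    labels = list(c("promoter", "intron", "gene_body"), character(0),
                  c("intron", "gene_body")),
    hosts = list("G1", character(0), "G2"),
    cgi = FALSE, intergenic = c(FALSE, TRUE, FALSE))
  fc <- exclusive_feature_class(ann)
  expect_equal(unname(fc), c("promoter", "intergenic", "intron"))
  # permuted precedence is honored
  fc2 <- exclusive_feature_class(ann, precedence = c("intron", "promoter",
                                                     "exon", "gene_body",
                                                     "intergenic"))
  expect_equal(unname(fc2["a"]), "intron")
})

test_that("sex chromosomes are dropped in both naming dialects", {
  man <- tibble::tibble(probe_id = paste0("p", 1:5),
                        chrom = c("chr1", "chrX", "chrY", "X", "Y"),
                        pos = 1:5 * 10L, strand = "+")
  expect_message(kept <- drop_sex_chromosomes(man), "4")
  expect_equal(kept$chrom, "chr1")
  auto <- man[1, ]
  expect_identical(drop_sex_chromosomes(auto), auto)
})
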