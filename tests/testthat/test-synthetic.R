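test_that("all generator stages are deterministic under a fixed seed", {
  cfg <- tiny_sim_config()
  g1 <- generate_genome_annotation(cfg, seed = 5L)
  g2 <- generate_genome_annotation(cfg, seed = 5L)
  expect_identical(g1, g2)
  t1 <- suppressMessages(generate_truth(g1, cfg, seed = 5L))
  t2 <- suppressMessages(generate_truth(g2, cfg, seed = 5L))
  expect_identical(t1$p_hmc, t2$p_hmc)
  o1 <- generate_observed(t1, cfg, seed = 5L)
  o2 <- generate_observed(t2, cfg, seed = 5L)
  expect_identical(o1$bs$m_signal, o2$bs$m_signal)
  expect_identical(o1$tab$detection_p, o2$tab$detection_p)
  s1 <- generate_gene_sets(g1, cfg, seed = 5L, truth = t1)
  s2 <- generate_gene_sets(g2, cfg, seed = 5L, truth = t2)
  expect_identical(s1, s2)
  # a different seed changes the data
  expect_false(identical(o1$bs$m_signal,
                         generate_observed(t1, cfg, seed = 6L)$bs$m_signal))
})

test_that("a gene-free genome yields only intergenic probes", {
  cfg <- tiny_sim_config(n_genes = 0L, probe_gene_weight = 0,
                         probe_cgi_weight = 0)
  g <- generate_genome_annotation(cfg, seed = 2L)
  expect_equal(nrow(g$genes), 0L)
  tr <- suppressMessages(suppressWarnings(generate_truth(g, cfg, seed = 2L)))
  expect_true(all(tr$annotation$intergenic))
})

test_that("a zero-effect configuration produces identical tumor and adjacent truth", {
  cfg <- tiny_sim_config(delta = 0, sigma_mc = 0, sigma_hmc = 0,
                         fraction_differential = 0)
  g <- generate_genome_annotation(cfg, seed = 3L)
  tr <- suppressMessages(generate_truth(g, cfg, seed = 3L))
  tum <- tr$units$tissue == "tumor"
  expect_equal(tr$p_hmc[, tum], tr$p_hmc[, !tum], ignore_attr = TRUE)
  expect_equal(tr$p_mc[, tum], tr$p_mc[, !tum], ignore_attr = TRUE)
})

test_that("truth marginals match the configured structure", {
  cfg <- sim_config(n_probes = 6000L, n_subjects = 10L, n_genes = 250L,
                    n_controls = 60L)
  g <- generate_genome_annotation(cfg, seed = 13L)
  tr <- suppressMessages(generate_truth(g, cfg, seed = 13L))

  # negative-dependence recount across units, per probe
  cx <- tr$p_mc - rowMeans(tr$p_mc)
  cy <- tr$p_hmc - rowMeans(tr$p_hmc)
  r <- rowSums(cx * cy) / sqrt(rowSums(cx^2) * rowSums(cy^2))
  expect_lt(abs(mean(r < 0) - cfg$frac_negative_coupling), 0.05)

  # gene-body 5hmC enrichment near the configured factor (non-planted probes)
  ok <- !tr$probes$planted
  gb <- mean(tr$p_hmc[ok & tr$probes$gene_body, ])
  ig <- mean(tr$p_hmc[ok & !tr$probes$gene_body & !tr$probes$cgi, ])
  expect_lt(abs(gb / ig - cfg$hmc_gene_body_factor), 0.5)

  # 5mC bimodal, 5hmC low-unimodal
  m_mc <- find_beta_modes(as.vector(tr$p_mc), min_mass = 0.01)
  expect_lt(min(m_mc$mode), 0.2)
  expect_gt(max(m_mc$mode), 0.8)
  expect_lt(median(tr$p_hmc), 0.2)

  # planted loci: loss:gain ratio and tissue shift
  expect_equal(sum(tr$probes$planted),
               round(cfg$fraction_differential * cfg$n_probes))
  expect_equal(mean(tr$probes$direction[tr$probes$planted] == "loss"), 0.9,
               tolerance = 0.02)
  loss <- tr$probes$direction == "loss"
  tum <- tr$units$tissue == "tumor"
  shift <- rowMeans(tr$p_hmc[loss, tum]) - rowMeans(tr$p_hmc[loss, !tum])
  expect_equal(mean(shift), -cfg$delta, tolerance = 0.02)
})

test_that("planted low-quality probes are exactly the ones the filter recovers", {
  cfg <- tiny_sim_config(fraction_low_quality = 0.05)
  g <- generate_genome_annotation(cfg, seed = 8L)
  tr <- suppressMessages(generate_truth(g, cfg, seed = 8L))
  obs <- generate_observed(tr, cfg, seed = 8L)
  for (ch in c("bs", "tab")) {
    found <- detection_filter(obs[[ch]]$detection_p, 1e-6, 0.05)
    expect_setequal(found, obs$low_quality[[toupper(ch)]])
  }
})

test_that("gene-set labels are enriched among planted hosts by the configured factor", {
  cfg <- sim_config(n_probes = 5000L, n_subjects = 6L, n_genes = 400L,
                    n_controls = 60L, gene_set_enrichment_factor = 3)
  g <- generate_genome_annotation(cfg, seed = 17L)
  tr <- suppressMessages(generate_truth(g, cfg, seed = 17L))
  gs <- generate_gene_sets(g, cfg, seed = 17L, truth = tr)
  unfav <- filter_prognostic(gs, 1e-3, "unfavorable")$gene
  loss_hosts <- unique(unlist(tr$probes$hosts[tr$probes$direction == "loss"]))
  other <- setdiff(g$genes$gene, unique(unlist(
    tr$probes$hosts[tr$probes$planted])))
  rate_hosts <- mean(loss_hosts %in% unfav)
  rate_other <- mean(other %in% unfav)
  expect_gt(rate_hosts / rate_other, 1.6)   # well above the null ratio of 1

  # the strict 0.001 filter retains exactly the sub-threshold entries
  expect_true(all(filter_prognostic(gs, 1e-3)$logrank_p < 1e-3))
  prognostic <- gs[gs$category == "prognostic" & !is.na(gs$logrank_p), ]
  expect_equal(nrow(filter_prognostic(gs, 1e-3)),
               sum(prognostic$logrank_p < 1e-3))

  # a factor of 1 is the null configuration: labels independent of planting
  cfg0 <- sim_config(n_probes = 5000L, n_subjects = 6L, n_genes = 400L,
                     n_controls = 60L, gene_set_enrichment_factor = 1)
  gs0 <- generate_gene_sets(g, cfg0, seed = 17L, truth = tr)
  gs0b <- generate_gene_sets(g, cfg0, seed = 17L, truth = NULL)
  expect_identical(gs0, gs0b)
})

test_that("emitted study files are accepted back by the readers unchanged", {
  cfg <- tiny_sim_config()
  sim <- suppressMessages(simulate_tab_study(cfg, seed = 9L))
  d <- withr::local_tempdir()
  write_simulated_study(sim, d)
  sheet <- read_sample_sheet(file.path(d, "sample_sheet.tsv"))
  bs <- read_channel_matrix(file.path(d, "bs_m_signal.tsv"), "BS",
                            layout = "signal",
                            u_path = file.path(d, "bs_u_signal.tsv"),
                            detection_p_path = file.path(d, "bs_detection_p.tsv"),
                            sample_sheet = sheet)
  expect_identical(bs$m_signal, sim$observed$bs$m_signal)
  man <- read_probe_manifest(file.path(d, "probe_manifest.tsv"))
  expect_equal(man, sim$genome$manifest)
  cgi <- read_bed(file.path(d, "cgi.bed"))
  expect_equal(cgi$start, sim$genome$cgi$start)
  gs <- read_gene_sets(file.path(d, "gene_sets.tsv"))
  expect_equal(nrow(gs), nrow(sim$gene_sets))

  # writing twice from the same seed gives byte-identical files
  d2 <- withr::local_tempdir()
  write_simulated_study(suppressMessages(simulate_tab_study(cfg, seed = 9L)), d2)
  for (f in list.files(d)) {
    expect_identical(readLines(file.path(d, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})
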