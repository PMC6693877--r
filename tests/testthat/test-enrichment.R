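test_that("the Fisher 2x2 construction reproduces the worked example", {
  bg <- sprintf("p%03d", 1:100)
  labelled <- bg[1:10]
  set5 <- c(bg[1:3], bg[98:99])   # 3 labelled of 5
  rec <- fisher_enrichment(set5, bg, labelled)
  expect_equal(c(rec$a, rec$b, rec$c, rec$d), c(3, 2, 7, 88))
  expect_equal(rec$odds_ratio, 264 / 14)
  expect_equal(rec$odds_ratio, 18.857, tolerance = 1e-4)
  expect_equal(rec$p_enrichment, enum_hyper_upper(3, 10, 100, 5), tolerance = 1e-12)
  expect_equal(rec$p_enrichment, 0.00664, tolerance = 1e-3)
  expect_equal(rec$p_one_sided, rec$p_enrichment)
})

test_that("Fisher odds ratios hit 1 for proportional tables and +Inf at the boundary", {
  bg <- sprintf("p%03d", 1:120)
  labelled <- c(bg[1:5], bg[21:35])          # 5/20 in set, 15/60... construct:
  set20 <- bg[1:20]                          # a=5, b=15; complement: c=15, d=85
  rec <- fisher_enrichment(set20, bg, c(bg[1:5], bg[21:35]))
  expect_equal(rec$a / (rec$a + rec$b), 0.25)

  # proportional: label rate identical in set and complement -> OR = 1
  rec1 <- fisher_enrichment(bg[1:20], bg, c(bg[1:5], bg[21:45]))
  expect_equal(rec1$odds_ratio, 1)

  # every set probe labelled and label rare outside: OR = Inf, p = point mass
  rec2 <- fisher_enrichment(bg[1:4], bg, bg[1:4])
  expect_equal(rec2$odds_ratio, Inf)
  expect_equal(rec2$p_enrichment, dhyper(4, 4, 116, 4), tolerance = 1e-12)

  # depletion is read from the lower tail with OR < 1
  rec3 <- fisher_enrichment(bg[61:120], bg, bg[1:50])
  expect_lt(rec3$odds_ratio, 1)
  expect_equal(rec3$p_one_sided, rec3$p_depletion)
  expect_error(fisher_enrichment(character(), bg, labelled), "empty")
})

test_that("Fisher tails equal exhaustive hypergeometric enumeration (N <= 30 sweep)", {
  for (N in c(5, 12, 30)) {
    bg <- sprintf("x%03d", 1:N)
    for (K in 1:(N - 1)) {
      for (n_set in 1:(N - 1)) {
        labelled <- bg[seq_len(K)]
        a <- max(0, K + n_set - N):min(K, n_set)
        for (aa in a) {
          set <- c(head(labelled, aa), head(setdiff(bg, labelled), n_set - aa))
          rec <- fisher_enrichment(set, bg, labelled)
          expect_equal(rec$p_enrichment, enum_hyper_upper(aa, K, N, n_set),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("probe sets map to deduplicated host-gene unions", {
  ann <- six_probe_annotation()
  ann$hosts[[2]] <- c("g1", "g2")
  expect_equal(map_set_to_genes(c("p1", "p2"), ann), c("g1", "g2"))
  expect_equal(map_set_to_genes(c("p2", "p1"), ann), c("g1", "g2"))
  ann$hosts[[1]] <- character(0)
  expect_equal(map_set_to_genes("p1", ann), character(0))
})

test_that("permutation empirical p converges to the enumerated exact value", {
  ann <- six_probe_annotation()
  # all 15 unordered pairs; count > 1 only for pairs hitting both g1 and g2:
  # {p1,p3}, {p2,p3} -> exact P(count > 1) = 2/15
  pr <- permutation_enrichment(c("p1", "p4"), ann, c("g1", "g2"),
                               n_perm = 20000L, seed = 99L)
  expect_equal(pr$observed, 1L)
  p_exact <- 2 / 15
  se <- sqrt(p_exact * (1 - p_exact) / pr$n_perm)
  expect_lt(abs(pr$empirical_p - p_exact), 3 * se)

  # greater-or-equal rule with observed 2: P(count >= 2) = 2/15
  pr2 <- permutation_enrichment(c("p1", "p3"), ann, c("g1", "g2"),
                                n_perm = 20000L, seed = 99L,
                                rule = "greater_or_equal")
  expect_equal(pr2$observed, 2L)
  expect_lt(abs(pr2$empirical_p - p_exact), 3 * se)

  # the strict rule at the maximum attainable count gives p = 0
  pr3 <- permutation_enrichment(c("p1", "p3"), ann, c("g1", "g2"),
                                n_perm = 2000L, seed = 1L)
  expect_equal(pr3$empirical_p, 0)
  # small-sample correction keeps p positive
  pr4 <- permutation_enrichment(c("p1", "p3"), ann, c("g1", "g2"),
                                n_perm = 2000L, seed = 1L, add_one = TRUE)
  expect_equal(pr4$empirical_p, 1 / 2001)
})

test_that("permutation nulls are bit-identical under a fixed seed", {
  ann <- six_probe_annotation()
  a <- permutation_enrichment(c("p1", "p4"), ann, c("g1", "g2"),
                              n_perm = 5000L, seed = 7L)
  b <- permutation_enrichment(c("p1", "p4"), ann, c("g1", "g2"),
                              n_perm = 5000L, seed = 7L)
  expect_identical(a$null_counts, b$null_counts)
  c_ <- permutation_enrichment(c("p1", "p4"), ann, c("g1", "g2"),
                               n_perm = 5000L, seed = 8L)
  expect_false(identical(a$null_counts, c_$null_counts))
  expect_error(permutation_enrichment(paste0("p", 1:7), ann, "g1"),
               "larger than")
})

test_that("directional runs cover direction x gene-set combinations and skip empties", {
  set.seed(44)
  n <- 400
  genes <- sprintf("G%03d", 1:60)
  ann <- tibble::tibble(
    probe_id = sprintf("p%04d", 1:n),
    labels = replicate(n, "gene_body", simplify = FALSE),
    hosts = lapply(sample(genes, n, replace = TRUE), identity),
    cgi = FALSE, intergenic = FALSE)
  gs <- tibble::tibble(
    gene = genes[1:30],
    category = rep(c("prognostic", "elevated"), 15),
    direction = rep(c("unfavorable", "none"), 15),
    logrank_p = rep(c(1e-4, NA), 15))
  split <- list(lower_in_tumor = ann$probe_id[1:40],
                higher_in_tumor = character(0))
  expect_message(
    runs <- directional_subsets(split, ann, gs, n_perm = 300L, seed = 5L),
    "skipping")
  expect_true(all(runs$direction == "lower_in_tumor"))
  expect_setequal(runs$gene_set, c("unfavorable", "elevated"))
  expect_true(all(runs$empirical_p >= 0 & runs$empirical_p <= 1))
  expect_s3_class(runs$result[[1]], "permutation_result")
  g <- glance(runs$result[[1]])
  expect_equal(g$n_perm, 300L)
})

test_that("null-target empirical p-values are near-uniform", {
  set.seed(45)
  n <- 600
  genes <- sprintf("G%03d", 1:80)
  ann <- tibble::tibble(
    probe_id = sprintf("p%04d", 1:n),
    labels = replicate(n, "gene_body", simplify = FALSE),
    hosts = lapply(sample(genes, n, replace = TRUE), identity),
    cgi = FALSE, intergenic = FALSE)
  ps <- vapply(1:60, function(r) {
    target <- sample(genes, 25)
    set <- sample(ann$probe_id, 30)
    pr <- permutation_enrichment(set, ann, target, n_perm = 400L,
                                 seed = 1000L + r)
    # randomized-PIT p: exactly uniform under exchangeability, free of the
    # lattice discreteness of the raw empirical p
    (sum(pr$null_counts > pr$observed) +
       runif(1) * (sum(pr$null_counts == pr$observed) + 1)) / (pr$n_perm + 1)
  }, numeric(1))
  # coarse uniformity: mean near 1/2 and mass in both halves
  expect_gt(mean(ps < 0.5), 0.25)
  expect_lt(mean(ps < 0.5), 0.75)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
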