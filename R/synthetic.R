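# Seeded synthetic-data generator. Emulates the statistical structure of a
# paired tumor/adjacent TAB-array study: a small synthetic genome with gene
# models, CpG islands and histone gapped peaks; per-unit (5mC, 5hmC) truth
# with a bimodal 5mC marginal, a low unimodal 5hmC marginal, predominantly
# negative per-CpG 5mC-5hmC dependence and gene-body 5hmC enrichment;
# loss-dominant planted tumor-vs-adjacent 5hmC differences; and BS/TAB
# signal-pair observations with binomial pseudo-count noise plus Gaussian
# background matched to the normexp correction model.

#' Generator configuration
#'
#' Defaults describe the emulated study: 17 tumor/adjacent pairs measured
#' on both channels, 20,000 probes, 2.5% planted differential loci with a
#' 9:1 loss:gain ratio and effect size 0.15 on the 5hmC beta scale, 80%
#' negatively 5mC-coupled probes, pseudo-depth 2,000, and 1% planted
#' low-quality probes per channel.
#'
#' @param n_probes Total probes (a small fraction goes to chrX/chrY).
#' @param n_subjects Tumor/adjacent pairs, default 17.
#' @param n_genes Genes in the synthetic genome.
#' @param cgi_tss_fraction Fraction of genes with a CpG island at the TSS.
#' @param probe_cgi_weight,probe_gene_weight Placement probabilities for a
#'   probe to target a CpG island / a gene body (remainder uniform).
#' @param mc_low_shape,mc_high_shape Beta shapes of the low and high 5mC
#'   mixture components.
#' @param mc_low_weight_cgi,mc_low_weight_other P(low component) for CGI /
#'   non-CGI probes.
#' @param hmc_shape1,hmc_shape2 Beta shapes of the baseline 5hmC level.
#' @param hmc_gene_body_factor Multiplier on the mean 5hmC of gene-body
#'   probes.
#' @param frac_negative_coupling Fraction of probes whose per-unit 5hmC is
#'   negatively coupled to 5mC.
#' @param coupling_negative,coupling_positive Logit-scale coupling strengths.
#' @param sigma_mc,sigma_hmc Logit-scale unit-to-unit biological SDs.
#' @param fraction_differential Fraction of autosomal probes planted as
#'   differential.
#' @param loss_fraction Fraction of planted loci that lose 5hmC in tumor.
#' @param delta Planted effect size on the 5hmC beta scale.
#' @param pseudo_depth Binomial pseudo-depth w of the channel measurements.
#' @param intensity_scale Signal intensity corresponding to full depth.
#' @param bg_mean,bg_sd Gaussian background intensity parameters.
#' @param fraction_low_quality Fraction of probes planted low-quality per
#'   channel.
#' @param n_controls Negative-control probes per channel.
#' @param prognostic_sig_rate Baseline rate of genes with a significant
#'   (log-rank p < 0.001) prognostic label, per direction.
#' @param prognostic_ns_rate Rate of additional non-significant prognostic
#'   entries.
#' @param elevated_rate Baseline rate of the elevated label.
#' @param gene_set_enrichment_factor Multiplier on the label rates among
#'   planted-loci host genes (loss hosts for unfavorable, gain hosts for
#'   favorable, all planted hosts for elevated).
#' @param sex_probe_fraction,sex_gene_fraction Share of probes / genes on
#'   chrX+chrY.
#' @param background_model `"normal"` (matched to the normexp correction)
#'   or `"t"` (heavy-tailed background for robustness checks).
#' @return A named list of class `hmc_sim_config`.
#' @export
sim_config <- function(n_probes = 20000L,
                       n_subjects = 17L,
                       n_genes = 600L,
                       cgi_tss_fraction = 0.7,
                       probe_cgi_weight = 0.30,
                       probe_gene_weight = 0.45,
                       mc_low_shape = c(2, 12),
                       mc_high_shape = c(10, 2.5),
                       mc_low_weight_cgi = 0.8,
                       mc_low_weight_other = 0.45,
                       hmc_shape1 = 1.3,
                       hmc_shape2 = 20,
                       hmc_gene_body_factor = 2.0,
                       frac_negative_coupling = 0.8,
                       coupling_negative = 1.0,
                       coupling_positive = 0.2,
                       sigma_mc = 0.25,
                       sigma_hmc = 0.05,
                       fraction_differential = 0.025,
                       loss_fraction = 0.9,
                       delta = 0.15,
                       pseudo_depth = 2000L,
                       intensity_scale = 5000,
                       bg_mean = 100,
                       bg_sd = 10,
                       fraction_low_quality = 0.01,
                       n_controls = 600L,
                       prognostic_sig_rate = 0.06,
                       prognostic_ns_rate = 0.13,
                       elevated_rate = 0.15,
                       gene_set_enrichment_factor = 3,
                       sex_probe_fraction = 0.02,
                       sex_gene_fraction = 0.04,
                       background_model = c("normal", "t")) {
  cfg <- as.list(environment())
  cfg$background_model <- match.arg(background_model)
  fracs <- c(cfg$cgi_tss_fraction, cfg$probe_cgi_weight, cfg$probe_gene_weight,
             cfg$mc_low_weight_cgi, cfg$mc_low_weight_other,
             cfg$frac_negative_coupling, cfg$fraction_differential,
             cfg$loss_fraction, cfg$fraction_low_quality,
             cfg$sex_probe_fraction, cfg$sex_gene_fraction)
  if (any(fracs < 0 | fracs > 1)) hmc_abort("fractions must lie in [0, 1]")
  if (cfg$delta < 0 || cfg$delta > 1) hmc_abort("`delta` must lie in [0, 1]")
  structure(cfg, class = c("hmc_sim_config", "list"))
}

with_seed <- function(seed, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  code
}

#' Generate a synthetic genome annotation
#'
#' Places non-overlapping genes (with exon/intron structure) on synthetic
#' chromosomes (four autosomes plus small chrX/chrY), CpG islands
#' preferentially at TSSs, six histone-mark gapped-peak tracks with
#' per-mark placement biases, and probes with CpG-island-dense placement.
#'
#' @param config An [sim_config()].
#' @param seed Integer seed; the output is fully deterministic given it.
#' @return List: `manifest` (probe tibble), `genes`, `exons`, `cgi`,
#'   `histone` (interval tibbles), `chrom_lengths` (named vector).
#' @export
generate_genome_annotation <- function(config = sim_config(), seed = 1L) {
  with_seed(seed, {
    chroms <- c("chr1", "chr2", "chr3", "chr4", "chrX", "chrY")
    gene_w <- c(rep((1 - config$sex_gene_fraction) / 4, 4),
                config$sex_gene_fraction * 0.8, config$sex_gene_fraction * 0.2)
    n_per <- as.vector(stats::rmultinom(1, config$n_genes, gene_w))
    genes_l <- list(); exons_l <- list(); lens <- setNames(numeric(6), chroms)
    gid <- 0L
    for (ci in seq_along(chroms)) {
      pos <- 10000L
      for (g in seq_len(max(n_per[ci], 0))) {
        gid <- gid + 1L
        glen <- as.integer(round(runif(1, 4000, 30000)))
        gap <- as.integer(round(runif(1, 4000, 20000)))
        gname <- sprintf("G%04d", gid)
        gstart <- pos; gend <- pos + glen
        strand <- sample(c("+", "-"), 1)
        n_ex <- sample(3:8, 1)
        # exon/intron structure: alternating partition of the gene span
        cuts <- sort(sample(seq(gstart + 50L, gend - 50L), 2L * n_ex - 2L))
        bounds <- c(gstart, cuts, gend)
        ex_start <- bounds[seq(1, length(bounds) - 1, by = 2)]
        ex_end <- bounds[seq(2, length(bounds), by = 2)]
        genes_l[[gid]] <- tibble(gene = gname, chrom = chroms[ci],
                                 strand = strand, start = gstart, end = gend)
        exons_l[[gid]] <- tibble(gene = gname, chrom = chroms[ci],
                                 start = as.integer(ex_start),
                                 end = as.integer(ex_end))
        pos <- gend + gap
      }
      lens[ci] <- pos + 50000L
    }
    empty_genes <- tibble(gene = character(), chrom = character(),
                          strand = character(), start = integer(),
                          end = integer())
    genes <- bind_rows(c(list(empty_genes), genes_l))
    exons <- bind_rows(c(list(empty_genes[, c("gene", "chrom", "start", "end")]),
                         exons_l))

    # CpG islands: at TSSs of a fraction of genes, plus random islands
    tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
    at_tss <- runif(nrow(genes)) < config$cgi_tss_fraction
    cgi_tss <- tibble(chrom = genes$chrom[at_tss],
                      start = pmax(0L, as.integer(tss[at_tss] - round(runif(sum(at_tss), 200, 800)))),
                      end = as.integer(tss[at_tss] + round(runif(sum(at_tss), 200, 800))),
                      label = "CGI")
    n_rand_cgi <- max(1L, as.integer(0.3 * nrow(genes)))
    rc_chrom <- sample(chroms, n_rand_cgi, replace = TRUE, prob = lens / sum(lens))
    rc_start <- as.integer(round(runif(n_rand_cgi, 0, lens[rc_chrom] - 2000)))
    cgi <- bind_rows(cgi_tss,
                     tibble(chrom = rc_chrom, start = rc_start,
                            end = rc_start + as.integer(round(runif(n_rand_cgi, 400, 1500))),
                            label = "CGI")) %>%
      arrange(.data$chrom, .data$start)

    # histone gapped-peak tracks; gene_bias = P(peak centered in a gene span)
    marks <- tibble(
      mark = c("H3K4me1", "H3K27ac", "H3K36me3", "H3K4me3", "H3K27me3", "H3K9me3"),
      n_peaks = as.integer(round(config$n_genes * c(1.2, 0.8, 0.9, 0.6, 0.5, 0.4))),
      gene_bias = c(0.55, 0.65, 0.90, 0.85, 0.30, 0.10),
      at_tss = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
    histone_l <- purrr::pmap(marks, function(mark, n_peaks, gene_bias, at_tss) {
      in_gene <- runif(n_peaks) < gene_bias
      gsel <- sample.int(nrow(genes), n_peaks, replace = TRUE)
      center <- ifelse(
        in_gene,
        if (at_tss) tss[gsel] + round(runif(n_peaks, -500, 500))
        else round(genes$start[gsel] + runif(n_peaks) * (genes$end[gsel] - genes$start[gsel])),
        NA)
      chrom <- ifelse(in_gene, genes$chrom[gsel],
                      sample(chroms, n_peaks, replace = TRUE, prob = lens / sum(lens)))
      center[!in_gene] <- round(runif(sum(!in_gene), 3000, lens[chrom[!in_gene]] - 3000))
      hw <- round(runif(n_peaks, 500, 2500))
      tibble(chrom = chrom, start = as.integer(pmax(0, center - hw)),
             end = as.integer(center + hw), label = mark)
    })
    histone <- bind_rows(histone_l) %>% arrange(.data$label, .data$chrom, .data$start)

    # probes: CpG-dense placement (islands, then gene bodies, then uniform)
    n_sex <- as.integer(round(config$n_probes * config$sex_probe_fraction))
    n_auto <- config$n_probes - n_sex
    place <- function(n, chrom_pool) {
      u <- runif(n)
      cgi_pool <- which(cgi$chrom %in% chrom_pool)
      gene_pool <- which(genes$chrom %in% chrom_pool)
      in_cgi <- u < config$probe_cgi_weight & length(cgi_pool) > 0
      in_gene <- !in_cgi & u < config$probe_cgi_weight + config$probe_gene_weight &
        length(gene_pool) > 0
      chrom <- character(n); pos <- integer(n)
      if (any(in_cgi)) {
        ii <- sample(cgi_pool, sum(in_cgi), replace = TRUE)
        chrom[in_cgi] <- cgi$chrom[ii]
        pos[in_cgi] <- as.integer(floor(cgi$start[ii] +
          runif(sum(in_cgi)) * (cgi$end[ii] - cgi$start[ii]))) + 1L
      }
      if (any(in_gene)) {
        ii <- sample(gene_pool, sum(in_gene), replace = TRUE)
        chrom[in_gene] <- genes$chrom[ii]
        pos[in_gene] <- as.integer(floor(genes$start[ii] +
          runif(sum(in_gene)) * (genes$end[ii] - genes$start[ii]))) + 1L
      }
      rest <- !(in_cgi | in_gene)
      if (any(rest)) {
        cc <- sample(chrom_pool, sum(rest), replace = TRUE,
                     prob = lens[chrom_pool] / sum(lens[chrom_pool]))
        chrom[rest] <- cc
        pos[rest] <- as.integer(floor(runif(sum(rest)) * (lens[cc] - 1))) + 1L
      }
      tibble(chrom = chrom, pos = pos)
    }
    probes <- bind_rows(place(n_auto, c("chr1", "chr2", "chr3", "chr4")),
                        place(n_sex, c("chrX", "chrY")))
    manifest <- tibble(probe_id = sprintf("cg%07d", seq_len(nrow(probes))),
                       chrom = probes$chrom, pos = probes$pos,
                       strand = sample(c("+", "-"), nrow(probes), replace = TRUE))
    list(manifest = manifest, genes = genes, exons = exons, cgi = cgi,
         histone = histone, chrom_lengths = lens)
  })
}

#' Generate per-unit modification truth with planted differences
#'
#' Draws probe-level 5mC means from a two-component Beta mixture (CGI
#' probes biased to the low mode) and 5hmC means from a low-mean Beta
#' (gene-body probes elevated by the configured factor); per-unit values
#' jitter around the probe means on the logit scale, with 5hmC coupled to
#' the 5mC jitter with a negative sign for the configured fraction of
#' probes. Tumor 5hmC means of planted loci are shifted by -delta (losses)
#' or +delta (gains); values are clipped to the simplex with a logged count.
#'
#' @param genome Output of [generate_genome_annotation()].
#' @param config An [sim_config()].
#' @param seed Integer seed.
#' @param run_config An [hmc_config()] (promoter window for the annotation).
#' @return A `truth_table`: list with `units` (tibble), `p_mc`, `p_hmc`
#'   (probe x unit matrices of true levels), `probes` (tibble: probe_id,
#'   planted flag, direction, delta, cgi / gene_body flags, hosts),
#'   `annotation` (the `annotation_table` used), `n_clipped`.
#' @export
generate_truth <- function(genome, config = sim_config(), seed = 1L,
                           run_config = hmc_config()) {
  annotation <- annotate_probes(genome$manifest, genome$genes, genome$exons,
                                cgi = genome$cgi, histone = genome$histone,
                                config = run_config)
  with_seed(seed + 1L, {
    n <- nrow(genome$manifest)
    probe_id <- genome$manifest$probe_id
    gene_body <- vapply(annotation$labels, function(l) "gene_body" %in% l, logical(1))
    cgi <- annotation$cgi
    autosomal <- !genome$manifest$chrom %in% c("chrX", "chrY", "X", "Y")

    # probe-level means
    p_low <- ifelse(cgi, config$mc_low_weight_cgi, config$mc_low_weight_other)
    low <- runif(n) < p_low
    mc_mean <- ifelse(low,
                      rbeta(n, config$mc_low_shape[1], config$mc_low_shape[2]),
                      rbeta(n, config$mc_high_shape[1], config$mc_high_shape[2]))
    base_mean <- config$hmc_shape1 / (config$hmc_shape1 + config$hmc_shape2)
    gb_mean <- min(0.5, base_mean * config$hmc_gene_body_factor)
    gb_shape2 <- config$hmc_shape1 * (1 - gb_mean) / gb_mean
    hmc_mean <- ifelse(gene_body,
                       rbeta(n, config$hmc_shape1, gb_shape2),
                       rbeta(n, config$hmc_shape1, config$hmc_shape2))
    # damp 5hmC where 5mC is high: probe-level anticorrelation that keeps
    # the truth off the simplex boundary without distorting the gene-body /
    # intergenic mean ratio (the damping factor is independent of class)
    hmc_mean <- hmc_mean * (0.25 + 0.75 * (1 - mc_mean))

    # planted differential loci (autosomal only)
    n_diff <- min(as.integer(round(config$fraction_differential * n)),
                  sum(autosomal))
    planted <- sample(which(autosomal), n_diff)
    n_loss <- as.integer(round(config$loss_fraction * n_diff))
    loss <- planted[seq_len(n_loss)]
    gain <- setdiff(planted, loss)
    # losses need headroom to subtract delta; gains stay low so the shifted
    # mean remains in a realistic 5hmC range; planted loci sit at moderate
    # 5mC so the shifted truth stays on the simplex
    hmc_mean[loss] <- runif(length(loss), config$delta + 0.05, config$delta + 0.25)
    hmc_mean[gain] <- runif(length(gain), 0.03, 0.15)
    mc_mean[planted] <- pmin(mc_mean[planted],
                             runif(length(planted), 0.15, 0.45))
    direction <- rep("none", n)
    direction[loss] <- "loss"; direction[gain] <- "gain"
    delta_vec <- numeric(n)
    delta_vec[loss] <- -config$delta; delta_vec[gain] <- config$delta

    # per-unit truth
    subjects <- sprintf("S%02d", seq_len(config$n_subjects))
    units <- tibble(subject_id = rep(subjects, each = 2),
                    tissue = rep(c("adjacent", "tumor"), config$n_subjects)) %>%
      arrange(.data$subject_id, .data$tissue) %>%
      mutate(unit = paste(.data$subject_id, .data$tissue, sep = "."))
    n_units <- nrow(units)
    coupling_sign <- ifelse(runif(n) < config$frac_negative_coupling, -1, 1)
    coupling_strength <- ifelse(coupling_sign < 0, config$coupling_negative,
                                config$coupling_positive)
    clamp <- function(p) pmin(pmax(p, 1e-4), 1 - 1e-4)
    lo_mc <- stats::qlogis(clamp(mc_mean))
    p_mc <- matrix(0, n, n_units, dimnames = list(probe_id, units$unit))
    p_hmc <- p_mc
    n_clipped <- 0L
    for (j in seq_len(n_units)) {
      eps <- rnorm(n, 0, config$sigma_mc)
      m_j <- stats::plogis(lo_mc + eps)
      h_mean_j <- hmc_mean
      if (units$tissue[j] == "tumor") h_mean_j <- h_mean_j + delta_vec
      h_j <- stats::plogis(stats::qlogis(clamp(h_mean_j)) +
                             coupling_sign * coupling_strength * eps +
                             rnorm(n, 0, config$sigma_hmc))
      over <- m_j + h_j > 1
      n_clipped <- n_clipped + sum(over)
      h_j[over] <- pmax(0, 1 - m_j[over] - 1e-4)
      p_mc[, j] <- m_j; p_hmc[, j] <- h_j
    }
    if (n_clipped > 0)
      inform(sprintf("truth generator: clipped %d probe-unit values to the simplex", n_clipped))
    probes <- tibble(probe_id = probe_id, autosomal = autosomal,
                     planted = direction != "none", direction = direction,
                     delta = delta_vec, cgi = cgi, gene_body = gene_body,
                     coupling = coupling_sign,
                     hosts = annotation$hosts)
    structure(list(units = units, p_mc = p_mc, p_hmc = p_hmc, probes = probes,
                   annotation = annotation, n_clipped = n_clipped),
              class = "truth_table")
  })
}

#' Generate observed BS/TAB channel data from a truth table
#'
#' For each unit and channel, draws a binomial pseudo-count
#' x ~ Binomial(w, p_channel) with p_BS = p_5mC + p_5hmC and
#' p_TAB = p_5hmC, scales it into a signal pair on the intensity range, and
#' adds Gaussian background noise matched to the normexp model (or
#' heavy-tailed t background in the misspecified mode). Designated
#' low-quality probes receive failing detection p-values in more than 5%
#' of samples; negative-control intensities are emitted per channel.
#'
#' @param truth A `truth_table` from [generate_truth()].
#' @param config An [sim_config()].
#' @param seed Integer seed.
#' @return List: `bs`, `tab` ([channel_matrix()] with signal pairs and
#'   detection p), `controls_bs`, `controls_tab` (control x sample
#'   matrices), `sample_sheet`, `low_quality` (list of planted failing
#'   probe ids per channel).
#' @export
generate_observed <- function(truth, config = sim_config(), seed = 1L) {
  with_seed(seed + 2L, {
    units <- truth$units
    n <- nrow(truth$p_mc); n_units <- nrow(units)
    w <- config$pseudo_depth
    rbg <- function(nn) {
      if (config$background_model == "normal") rnorm(nn, config$bg_mean, config$bg_sd)
      else config$bg_mean + config$bg_sd * stats::rt(nn, df = 3)
    }
    make_channel <- function(assay) {
      p <- if (assay == "BS") pmin(truth$p_mc + truth$p_hmc, 1) else truth$p_hmc
      sample_id <- paste(units$unit, assay, sep = ".")
      x <- matrix(rbinom(n * n_units, w, as.vector(p)) / w, n, n_units)
      dn <- list(rownames(truth$p_mc), sample_id)
      m_sig <- matrix(pmax(0, config$intensity_scale * as.vector(x) + rbg(n * n_units)),
                      n, n_units, dimnames = dn)
      u_sig <- matrix(pmax(0, config$intensity_scale * (1 - as.vector(x)) + rbg(n * n_units)),
                      n, n_units, dimnames = dn)
      # detection p: clean cells are far below the 1e-6 threshold; planted
      # low-quality probes fail in a strict majority-exceeding fraction
      dp <- matrix(runif(n * n_units, 0, 1e-8), n, n_units,
                   dimnames = dimnames(m_sig))
      n_lq <- as.integer(round(config$fraction_low_quality * n))
      lq <- sample.int(n, n_lq)
      min_fail <- floor(0.05 * n_units) + 1L
      max_fail <- max(min_fail, ceiling(0.2 * n_units))
      for (i in lq) {
        n_bad <- min_fail + sample.int(max_fail - min_fail + 1L, 1) - 1L
        bad <- sample.int(n_units, n_bad)
        dp[i, bad] <- runif(length(bad), 0.01, 0.5)
      }
      controls <- matrix(pmax(0, rbg(config$n_controls * n_units)),
                         config$n_controls, n_units,
                         dimnames = list(sprintf("neg%04d", seq_len(config$n_controls)),
                                         sample_id))
      list(cm = channel_matrix(assay, m_signal = m_sig, u_signal = u_sig,
                               detection_p = dp),
           controls = controls,
           low_quality = rownames(truth$p_mc)[sort(lq)],
           sheet = tibble(sample_id = sample_id,
                          subject_id = units$subject_id,
                          tissue = units$tissue, assay = assay))
    }
    bs <- make_channel("BS"); tab <- make_channel("TAB")
    list(bs = bs$cm, tab = tab$cm,
         controls_bs = bs$controls, controls_tab = tab$controls,
         sample_sheet = bind_rows(bs$sheet, tab$sheet) %>%
           arrange(.data$subject_id, .data$tissue, .data$assay),
         low_quality = list(BS = bs$low_quality, TAB = tab$low_quality))
  })
}

#' Generate a synthetic gene-set table
#'
#' Assigns prognostic labels (favorable/unfavorable with log-rank p values
#' spanning the 0.001 screening threshold) and "elevated expression"
#' labels to the synthetic genes. When a truth table is supplied, label
#' rates among planted-loci host genes are multiplied by the configured
#' enrichment factor: unfavorable among loss-loci hosts, favorable among
#' gain-loci hosts, elevated among all planted hosts. Factor 1 gives a
#' null configuration (labels independent of planted loci).
#'
#' @param genome Output of [generate_genome_annotation()].
#' @param config An [sim_config()].
#' @param seed Integer seed.
#' @param truth Optional `truth_table` carrying the planted loci.
#' @return A gene-set tibble (`gene`, `category`, `direction`, `logrank_p`).
#' @export
generate_gene_sets <- function(genome, config = sim_config(), seed = 1L,
                               truth = NULL) {
  with_seed(seed + 3L, {
    genes <- genome$genes$gene
    f <- config$gene_set_enrichment_factor
    loss_hosts <- gain_hosts <- planted_hosts <- character()
    if (!is.null(truth) && f != 1) {
      loss_hosts <- unique(unlist(truth$probes$hosts[truth$probes$direction == "loss"]))
      gain_hosts <- unique(unlist(truth$probes$hosts[truth$probes$direction == "gain"]))
      planted_hosts <- union(loss_hosts, gain_hosts)
    }
    rate <- function(base, enriched_genes) {
      r <- rep(base, length(genes))
      r[genes %in% enriched_genes] <- min(1, base * f)
      r
    }
    unfav <- runif(length(genes)) < rate(config$prognostic_sig_rate, loss_hosts)
    fav <- !unfav & runif(length(genes)) < rate(config$prognostic_sig_rate, gain_hosts)
    ns_prog <- !unfav & !fav & runif(length(genes)) < config$prognostic_ns_rate
    elevated <- runif(length(genes)) < rate(config$elevated_rate, planted_hosts)
    sig_p <- function(nn) 10^runif(nn, -6, log10(1e-3))  # strictly below 1e-3
    ns_p <- function(nn) 10^runif(nn, log10(1.0001e-3), 0)
    rows <- list(
      tibble(gene = genes[unfav], category = "prognostic",
             direction = "unfavorable", logrank_p = sig_p(sum(unfav))),
      tibble(gene = genes[fav], category = "prognostic",
             direction = "favorable", logrank_p = sig_p(sum(fav))),
      tibble(gene = genes[ns_prog], category = "prognostic",
             direction = sample(c("favorable", "unfavorable"), sum(ns_prog),
                                replace = TRUE),
             logrank_p = ns_p(sum(ns_prog))),
      tibble(gene = genes[elevated], category = "elevated",
             direction = "none", logrank_p = NA_real_))
    bind_rows(rows) %>% arrange(.data$gene, .data$category)
  })
}

#' Simulate a complete synthetic TAB-array study
#'
#' Runs all four generator stages under one seed and returns everything
#' the pipeline consumes.
#'
#' @param config An [sim_config()].
#' @param seed Integer master seed (stage seeds are derived from it).
#' @param run_config An [hmc_config()].
#' @return List: `genome`, `truth`, `observed`, `gene_sets`, `config`, `seed`.
#' @export
simulate_tab_study <- function(config = sim_config(), seed = 1L,
                               run_config = hmc_config()) {
  genome <- generate_genome_annotation(config, seed)
  truth <- generate_truth(genome, config, seed, run_config)
  observed <- generate_observed(truth, config, seed)
  gene_sets <- generate_gene_sets(genome, config, seed, truth = truth)
  list(genome = genome, truth = truth, observed = observed,
       gene_sets = gene_sets, config = config, seed = seed)
}

#' Write a simulated study to disk in the package's file formats
#'
#' @param sim Output of [simulate_tab_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_study <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  readr::write_tsv(sim$genome$manifest, p("probe_manifest.tsv"), progress = FALSE)
  readr::write_tsv(sim$genome$genes, p("genes.tsv"), progress = FALSE)
  readr::write_tsv(sim$genome$exons, p("exons.tsv"), progress = FALSE)
  write_bed(sim$genome$cgi, p("cgi.bed"))
  write_bed(sim$genome$histone, p("histone_peaks.bed"))
  readr::write_tsv(sim$observed$sample_sheet, p("sample_sheet.tsv"), progress = FALSE)
  for (ch in c("bs", "tab")) {
    cm <- sim$observed[[ch]]
    write_channel_matrix(cm, p(paste0(ch, "_m_signal.tsv")),
                         u_path = p(paste0(ch, "_u_signal.tsv")),
                         detection_p_path = p(paste0(ch, "_detection_p.tsv")))
    write_tsv_matrix(sim$observed[[paste0("controls_", ch)]],
                     p(paste0(ch, "_controls.tsv")))
  }
  readr::write_tsv(sim$gene_sets, p("gene_sets.tsv"), progress = FALSE)
  invisible(dir)
}
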