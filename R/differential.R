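# Paired tumor-vs-adjacent testing of 5hmC per probe, with optional
# empirical-Bayes variance moderation and Bonferroni family-wise control.

#' Paired per-probe test of tumor vs adjacent 5hmC
#'
#' For each probe, computes subject-wise differences d_i = beta_tumor,i -
#' beta_adjacent,i and the paired t statistic t = mean(d) / (sd(d)/sqrt(n))
#' with df = n - 1 and a two-sided p from the t distribution. With
#' `moderation = TRUE` (default) per-probe variances are shrunk toward a
#' common prior by empirical Bayes: the posterior variance is
#' s2_post = (d0 * s0^2 + (n-1) * s2) / (d0 + n - 1) and the moderated t
#' uses df = d0 + n - 1, with the prior (d0, s0^2) estimated by
#' moment-matching a scaled-F marginal on the observed s^2 (matching on
#' log s^2 via digamma/trigamma identities). Tests are on the beta scale.
#'
#' @param profile A `modification_profile` (5hmC tested).
#' @param moderation Moderate variances (default `TRUE`).
#' @param alpha Family-wise alpha for the Bonferroni selection column.
#' @return A tibble of class `hmc_differential`, one row per probe:
#'   `probe_id`, `delta` (mean tumor - adjacent difference), `t`, `df`,
#'   `p_value`, `p_bonferroni`, `significant`, `direction`
#'   (`lower_in_tumor` / `higher_in_tumor`), `degenerate` (zero-variance
#'   probe without moderation). Attributes: `n_pairs`, `moderation`,
#'   `d0`, `s0_sq`, `alpha`.
#' @export
paired_test <- function(profile, moderation = TRUE, alpha = 0.05) {
  units <- profile$units
  subj <- unique(units$subject_id)
  tum <- match(paste(subj, "tumor"), paste(units$subject_id, units$tissue))
  adj <- match(paste(subj, "adjacent"), paste(units$subject_id, units$tissue))
  if (anyNA(tum) || anyNA(adj))
    hmc_abort(paste0("subject missing a tissue: ",
                     paste(subj[is.na(tum) | is.na(adj)], collapse = ", ")))
  n <- length(subj)
  if (n < 2) hmc_abort("need >= 2 tumor/adjacent pairs")
  d <- profile$beta_5hmc[, tum, drop = FALSE] - profile$beta_5hmc[, adj, drop = FALSE]
  delta <- rowMeans(d)
  s2 <- rowSums((d - delta)^2) / (n - 1)
  degenerate <- s2 == 0
  d0 <- Inf; s0_sq <- NA_real_
  if (moderation) {
    prior <- fit_f_prior(s2, df = n - 1)
    d0 <- prior$d0; s0_sq <- prior$s0_sq
    s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2))
               else (d0 * s0_sq + (n - 1) * s2) / (d0 + n - 1)
    df_t <- d0 + n - 1
    tstat <- delta / sqrt(s2_post / n)
    p <- 2 * pt(abs(tstat), df = df_t, lower.tail = FALSE)
    degenerate <- rep(FALSE, length(s2))
  } else {
    tstat <- delta / sqrt(s2 / n)
    df_t <- n - 1
    p <- 2 * pt(abs(tstat), df = df_t, lower.tail = FALSE)
    # zero-variance probes: t is +-Inf or NaN; flag and pin p at the boundary
    p[degenerate & delta != 0] <- 0
    p[degenerate & delta == 0] <- 1
    tstat[degenerate & delta == 0] <- 0
  }
  res <- tibble(
    probe_id = rownames(profile$beta_5hmc),
    delta = unname(delta), t = unname(tstat),
    df = if (length(df_t) == 1) rep(df_t, length(delta)) else df_t,
    p_value = unname(p),
    p_bonferroni = unname(bonferroni(p)),
    degenerate = unname(degenerate)) %>%
    mutate(significant = .data$p_bonferroni < alpha,
           direction = if_else(.data$delta < 0, "lower_in_tumor", "higher_in_tumor"))
  structure(res, class = c("hmc_differential", class(res)),
            n_pairs = n, moderation = moderation, d0 = d0, s0_sq = s0_sq,
            alpha = alpha)
}

# Estimate the scaled-F prior (d0, s0^2) for sample variances s2 with df
# residual degrees of freedom, by matching the first two moments of
# log(s2): if s2 ~ s0^2 * F(df, d0) then
#   e = log(s2) - digamma(df/2) + log(df/2)
#   E[e] = log(s0^2) - digamma(d0/2) + log(d0/2)
#   Var[e] = trigamma(df/2) + trigamma(d0/2).
fit_f_prior <- function(s2, df) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2) return(list(d0 = Inf, s0_sq = mean(s2)))
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  ev <- mean((e - ebar)^2) * length(e) / (length(e) - 1)
  excess <- ev - trigamma(df / 2)
  if (excess <= 0)  # variances more concordant than chi-square sampling noise
    return(list(d0 = Inf, s0_sq = exp(ebar)))
  d0 <- 2 * trigamma_inverse(excess)
  s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Solve trigamma(y) = x for y > 0 by Newton iteration on 1/trigamma,
# which is nearly linear.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Bonferroni adjustment
#'
#' p_adj = min(1, m * p) with m the number of tests.
#'
#' @param p P-values in `[0, 1]`.
#' @param m Number of tests (default `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) hmc_abort("p-values must lie in [0, 1]")
  pmin(1, m * p)
}

#' Split selected probes by direction of change
#'
#' Partitions the significant probes by the sign of the tumor - adjacent
#' difference.
#'
#' @param records An `hmc_differential` tibble.
#' @param selection Probe ids to split (default: the Bonferroni-significant
#'   probes in `records`).
#' @return A list: `counts` (tibble with `direction`, `n`),
#'   `lower_in_tumor` and `higher_in_tumor` (probe-id vectors).
#' @export
direction_split <- function(records, selection = NULL) {
  if (is.null(selection)) selection <- records$probe_id[records$significant]
  sel <- records[records$probe_id %in% selection, ]
  lower <- sel$probe_id[sel$direction == "lower_in_tumor"]
  higher <- sel$probe_id[sel$direction == "higher_in_tumor"]
  list(counts = tibble(direction = c("lower_in_tumor", "higher_in_tumor"),
                       n = c(length(lower), length(higher))),
       lower_in_tumor = lower, higher_in_tumor = higher)
}

#' @export
tidy.hmc_differential <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a differential analysis
#'
#' @param x An `hmc_differential` tibble.
#' @param ... Unused.
#' @return Tibble with the number of probes tested, pairs, significant
#'   probes, losses/gains among them, moderation settings.
#' @export
glance.hmc_differential <- function(x, ...) {
  sel <- x[x$significant, ]
  tibble(n_probes = nrow(x),
         n_pairs = attr(x, "n_pairs"),
         n_significant = nrow(sel),
         n_lower_in_tumor = sum(sel$direction == "lower_in_tumor"),
         n_higher_in_tumor = sum(sel$direction == "higher_in_tumor"),
         moderation = attr(x, "moderation"),
         d0 = attr(x, "d0"), s0_sq = attr(x, "s0_sq"),
         alpha = attr(x, "alpha"))
}
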