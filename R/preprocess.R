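# Quality filtering, normexp background correction, quantile normalization
# and beta / M-value computation. BS and TAB channels are processed
# separately end-to-end and merged only at the MLE stage.

#' Detection-p quality filter
#'
#' A probe fails when its detection p exceeds `threshold` in strictly more
#' than `max_fraction` of samples (both comparisons strict), the standard
#' array low-quality rule.
#'
#' @param detection_p Probes x samples matrix of detection p-values.
#' @param threshold Detection p above this counts as a failing sample.
#' @param max_fraction Failing-sample fraction that must be strictly
#'   exceeded, in (0, 1).
#' @return Character vector of failed probe ids.
#' @export
detection_filter <- function(detection_p, threshold = 1e-6, max_fraction = 0.05) {
  if (!is.matrix(detection_p) || ncol(detection_p) == 0)
    hmc_abort("`detection_p` must be a matrix with at least one sample column")
  if (max_fraction <= 0 || max_fraction >= 1)
    hmc_abort("`max_fraction` must lie in (0, 1)")
  if (anyNA(detection_p)) hmc_abort("`detection_p` contains missing values")
  frac <- rowMeans(detection_p > threshold)
  rownames(detection_p)[frac > max_fraction]
}

#' Combine per-channel QC failures and remove them from both channels
#'
#' Low-quality probes detected in either channel are removed from both, so
#' the two channels keep a shared probe universe for the MLE stage.
#'
#' @param bs,tab [channel_matrix()] objects sharing a probe universe.
#' @param failed_bs,failed_tab Failed probe ids per channel (defaults:
#'   recomputed from each channel's `detection_p`).
#' @param threshold,max_fraction Passed to [detection_filter()] when
#'   failures are recomputed.
#' @return A list with elements `bs`, `tab` (filtered channels) and
#'   `qc_report`, a tibble with per-channel and union failure counts.
#' @export
combine_and_remove <- function(bs, tab, failed_bs = NULL, failed_tab = NULL,
                               threshold = 1e-6, max_fraction = 0.05) {
  if (!setequal(probe_ids(bs), probe_ids(tab)))
    hmc_abort("BS and TAB channels must share the probe universe")
  if (is.null(failed_bs))
    failed_bs <- detection_filter(bs$detection_p, threshold, max_fraction)
  if (is.null(failed_tab))
    failed_tab <- detection_filter(tab$detection_p, threshold, max_fraction)
  union_failed <- union(failed_bs, failed_tab)
  keep <- setdiff(probe_ids(bs), union_failed)
  subset_cm <- function(x) {
    x$m_signal <- x$m_signal[keep, , drop = FALSE]
    x$u_signal <- if (!is.null(x$u_signal)) x$u_signal[keep, , drop = FALSE]
    x$beta <- if (!is.null(x$beta)) x$beta[keep, , drop = FALSE]
    x$detection_p <- if (!is.null(x$detection_p)) x$detection_p[keep, , drop = FALSE]
    x
  }
  list(
    bs = subset_cm(bs), tab = subset_cm(tab),
    qc_report = tibble(
      channel = c("BS", "TAB", "union"),
      n_failed = c(length(failed_bs), length(failed_tab), length(union_failed)),
      failed_probes = list(sort(failed_bs), sort(failed_tab), sort(union_failed))))
}

#' Fit exponential-normal background parameters
#'
#' Models an observed intensity as signal plus background, X = S + B with
#' S ~ Exp(mean theta) and B ~ Normal(mu, sigma^2) truncated at zero.
#' mu and sigma come from the moments of negative-control intensities
#' (de-truncated so the underlying normal is recovered); theta comes from
#' the observed intensities by method of moments, theta = mean(X) - mu.
#'
#' @param observed Non-negative intensities of regular probes (one sample).
#' @param controls Negative-control probe intensities for the same sample.
#' @param theta_floor Lower bound on theta; used (with a warning) when
#'   `mean(observed) <= mu`, i.e. no detectable signal.
#' @return A list with `mu`, `sigma`, `theta` (`normexp_params`).
#' @export
fit_normexp <- function(observed, controls, theta_floor = 1) {
  if (length(controls) < 10)
    hmc_abort("need at least 10 negative-control intensities")
  if (any(observed < 0)) hmc_abort("observed intensities must be non-negative")
  mom <- detruncate_normal_moments(mean(controls), sd(controls))
  mu <- mom$mu; sigma <- mom$sigma
  theta <- mean(observed) - mu
  if (!is.finite(theta) || theta <= 0) {
    warn(sprintf("no detectable signal above background (mean observed %.3g <= mu %.3g); theta floored at %g",
                 mean(observed), mu, theta_floor))
    theta <- theta_floor
  }
  structure(list(mu = mu, sigma = sigma, theta = theta), class = "normexp_params")
}

# Invert the truncation: given the mean/sd of N(mu, sigma^2) truncated at 0,
# recover (mu, sigma) by solving the two truncated-normal moment equations.
# When truncation is negligible (mean >> sd) this returns the inputs.
detruncate_normal_moments <- function(m_tr, s_tr) {
  if (!is.finite(m_tr) || !is.finite(s_tr) || s_tr <= 0)
    hmc_abort("degenerate control distribution")
  if (m_tr > 6 * s_tr) return(list(mu = m_tr, sigma = s_tr))
  obj <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    a <- -mu / sigma
    lam <- exp(stats::dnorm(a, log = TRUE) - stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
    m <- mu + sigma * lam
    v <- sigma^2 * (1 + a * lam - lam^2)
    (m - m_tr)^2 / s_tr^2 + (sqrt(pmax(v, 0)) - s_tr)^2 / s_tr^2
  }
  fit <- stats::optim(c(m_tr, log(s_tr)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Background-correct intensities with the normexp posterior mean
#'
#' Returns E[S | X = x] under X = S + B, S ~ Exp(mean theta),
#' B ~ Normal(mu, sigma^2) — the numerically guarded closed form (log-space
#' error-function ratios). Strictly positive and increasing in x.
#'
#' @param x Observed intensities (any real values).
#' @param params A `normexp_params` list (`mu`, `sigma`, `theta`).
#' @return Corrected signal, same length as `x`.
#' @export
normexp_correct <- function(x, params) {
  limma::normexp.signal(c(params$mu, log(params$sigma), log(params$theta)),
                        as.vector(x))
}

#' Quantile-normalize a matrix across samples
#'
#' After normalization every column's sorted values equal the across-column
#' mean of order statistics; within-column ranks are preserved and ties are
#' averaged.
#'
#' @param m Probes x samples matrix with at least 2 columns.
#' @return The normalized matrix, same dimnames.
#' @export
quantile_normalize <- function(m) {
  if (!is.matrix(m) || ncol(m) < 2)
    hmc_abort("`m` must be a matrix with >= 2 sample columns")
  if (anyNA(m)) hmc_abort("`m` contains missing values")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Compute beta values from a signal pair
#'
#' beta = M / (M + U + offset), the standard array modification fraction;
#' the offset stabilizes low-intensity probes.
#'
#' @param m_signal,u_signal Non-negative methylated-/unmethylated-state
#'   intensities (vectors or matrices of equal shape).
#' @param offset Non-negative stabilizer, default 100.
#' @return beta values in `[0, 1]`, same shape as the inputs.
#' @export
compute_beta <- function(m_signal, u_signal, offset = 100) {
  if (any(m_signal < 0) || any(u_signal < 0))
    hmc_abort("signals must be non-negative")
  if (offset < 0) hmc_abort("`offset` must be non-negative")
  denom <- m_signal + u_signal + offset
  if (any(denom == 0))
    hmc_abort("both signals zero with zero offset: beta undefined")
  m_signal / denom
}

#' Convert beta values to M-values
#'
#' M = log2(beta / (1 - beta)), the variance-stabilized modification scale
#' conventionally used for heatmaps and linear modelling. beta is clamped
#' to `[eps, 1 - eps]` first so the transform is total.
#'
#' @param beta beta values in `[0, 1]`.
#' @param eps Clamp width, default 1e-6.
#' @return M-values, same shape as `beta`.
#' @export
beta_to_mvalue <- function(beta, eps = 1e-6) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Preprocess one assay channel end-to-end
#'
#' Runs the per-channel stage: normexp background correction of the
#' methylated and unmethylated signals (parameters fitted per sample from
#' the negative controls), quantile normalization of each signal matrix
#' across the channel's samples, then beta computation. Detection-p
#' filtering is applied jointly across channels by [combine_and_remove()],
#' so it is not repeated here.
#'
#' @param cm A [channel_matrix()] carrying a signal pair.
#' @param controls Negative-control intensities: a matrix with one column
#'   per sample of this channel (control probes x samples).
#' @param config An [hmc_config()].
#' @return A [channel_matrix()] carrying `beta` (detection_p passed through).
#' @export
preprocess_channel <- function(cm, controls, config = hmc_config()) {
  if (is.null(cm$m_signal))
    hmc_abort("`cm` must carry a signal pair (m_signal/u_signal)")
  sids <- sample_ids(cm)
  if (!all(sids %in% colnames(controls)))
    hmc_abort("`controls` must have a column per channel sample")
  corr <- function(sig) {
    out <- sig
    for (s in sids) {
      par <- fit_normexp(c(cm$m_signal[, s], cm$u_signal[, s]), controls[, s])
      out[, s] <- normexp_correct(sig[, s], par)
    }
    out
  }
  m <- quantile_normalize(corr(cm$m_signal))
  u <- quantile_normalize(corr(cm$u_signal))
  beta <- compute_beta(m, u, offset = config$beta_offset)
  channel_matrix(cm$assay, beta = beta, detection_p = cm$detection_p)
}
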