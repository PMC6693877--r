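# Independent oracles used across the suite. Each is a brute-force or
# closed-form route that never shares code with the implementation it checks.

# Profile-likelihood grid search for the constrained two-binomial MLE:
# for each p_hmc on a 1e-4 grid, the optimal p_mc given the simplex
# constraints has the closed per-coordinate form clamp(beta_bs - p_hmc);
# the 1D grid over p_hmc then scans the whole constrained simplex.
grid_mle_oracle <- function(beta_bs, beta_tab, w_bs = 1, w_tab = 1,
                            step = 1e-4) {
  loglik <- function(p_bs, p_tab) {
    term <- function(beta, w, p) {
      x <- beta * w
      x * log(pmax(p, 1e-300)) + (w - x) * log(pmax(1 - p, 1e-300))
    }
    term(beta_bs, w_bs, p_bs) + term(beta_tab, w_tab, p_tab)
  }
  ph <- seq(0, 1, by = step)
  pm <- pmin(pmax(beta_bs - ph, 0), 1 - ph)
  ll <- loglik(pm + ph, ph)
  i <- which.max(ll)
  c(beta_5mc = pm[i], beta_5hmc = ph[i])
}

# Posterior mean E[S | X = x] for X = S + B, S ~ Exp(theta),
# B ~ N(mu, sigma^2), by numerical quadrature over a window centered on
# the posterior mass (the integrand is concentrated near max(0, x - mu)).
quadrature_normexp <- function(x, mu, sigma, theta) {
  mode_s <- max(0, x - mu - sigma^2 / theta)
  lo <- max(0, mode_s - 12 * sigma)
  hi <- mode_s + 12 * sigma
  logf <- function(s) -s / theta - (x - s - mu)^2 / (2 * sigma^2)
  log0 <- logf(mode_s)  # normalize so the integrand is O(1) at its peak
  dens <- function(s) exp(logf(s) - log0)
  num <- stats::integrate(function(s) s * dens(s), lo, hi,
                          rel.tol = 1e-12, abs.tol = 0)$value
  den <- stats::integrate(dens, lo, hi, rel.tol = 1e-12, abs.tol = 0)$value
  num / den
}

# Linear-scan point-overlap oracle (0-based half-open intervals, 1-based
# probe positions).
linear_scan_overlap <- function(manifest, features) {
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    p0 <- manifest$pos[i] - 1L
    hit <- features$chrom == manifest$chrom[i] &
      features$start <= p0 & p0 < features$end
    if (any(hit))
      out[[length(out) + 1L]] <- tibble::tibble(
        probe_id = manifest$probe_id[i], label = features$label[hit])
  }
  if (length(out) == 0)
    return(tibble::tibble(probe_id = character(), label = character()))
  dplyr::bind_rows(out)
}

# Upper-tail hypergeometric probability P(X >= a) by explicit enumeration
# of the point masses.
enum_hyper_upper <- function(a, K, N, n) {
  xs <- max(a, 0):min(K, n)
  if (length(xs) == 0) return(0)
  sum(stats::dhyper(xs, K, N - K, n))
}

# Plain paired t-test recomputed per probe from first principles.
brute_paired_t <- function(diffs) {
  n <- length(diffs)
  m <- mean(diffs); s <- stats::sd(diffs)
  t <- m / (s / sqrt(n))
  list(delta = m, t = t, df = n - 1,
       p = 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE))
}
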