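test_that("detection filter applies the strict exceed-in-more-than-5%-of-samples rule", {
  n_samp <- 34
  dp <- matrix(0, 3, n_samp, dimnames = list(c("p1", "p2", "p3"), NULL))
  dp[1, 1:2] <- 1e-3   # 2/34 = 5.88% > 5% -> fails
  dp[2, 1] <- 1e-3     # 1/34 = 2.94% -> passes
  expect_equal(detection_filter(dp, 1e-6, 0.05), "p1")

  # boundary: exactly the threshold fraction passes (strict >)
  dp2 <- matrix(0, 1, 20, dimnames = list("q", NULL))
  dp2[1, 1] <- 1       # 1/20 = 0.05, not > 0.05
  expect_equal(detection_filter(dp2, 1e-6, 0.05), character(0))
  dp2[1, 2] <- 1       # 2/20 = 0.10 > 0.05
  expect_equal(detection_filter(dp2, 1e-6, 0.05), "q")

  expect_error(detection_filter(dp[, 0, drop = FALSE]), "sample")
})

test_that("detection filter agrees with per-probe brute-force counting", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 200; s <- sample(5:40, 1)
    dp <- matrix(10^runif(n * s, -9, 0), n, s,
                 dimnames = list(sprintf("p%03d", 1:n), NULL))
    thr <- 10^runif(1, -7, -1); frac <- runif(1, 0.02, 0.4)
    brute <- rownames(dp)[vapply(seq_len(n), function(i)
      sum(dp[i, ] > thr) / s > frac, logical(1))]
    expect_identical(detection_filter(dp, thr, frac), brute)
  }
})

test_that("QC failures are combined and removed from both channels", {
  ids <- sprintf("p%02d", 1:10)
  mk <- function(assay) {
    m <- matrix(runif(20), 10, 2, dimnames = list(ids, c("a", "b")))
    channel_matrix(assay, beta = m,
                   detection_p = matrix(0, 10, 2, dimnames = dimnames(m)))
  }
  set.seed(2)
  bs <- mk("BS"); tab <- mk("TAB")
  res <- combine_and_remove(bs, tab, failed_bs = c("p01", "p02"),
                            failed_tab = c("p02", "p03"))
  expect_setequal(probe_ids(res$bs), setdiff(ids, c("p01", "p02", "p03")))
  expect_identical(probe_ids(res$bs), probe_ids(res$tab))
  expect_equal(res$qc_report$n_failed, c(2L, 2L, 3L))
  # union contains each channel list
  expect_true(all(res$qc_report$failed_probes[[1]] %in%
                    res$qc_report$failed_probes[[3]]))
  # no failures -> identity
  res0 <- combine_and_remove(bs, tab, failed_bs = character(),
                             failed_tab = character())
  expect_identical(res0$bs$beta, bs$beta)
})

test_that("normexp parameters are recovered from simulated controls and signal", {
  set.seed(3)
  controls <- pmax(0, rnorm(10000, 100, 10))     # truncation negligible here
  observed <- rexp(10000, 1 / 500) + rnorm(10000, 100, 10)
  fit <- fit_normexp(observed, controls)
  expect_lt(abs(fit$mu - 100), 1)
  expect_lt(abs(fit$sigma - 10), 1)
  expect_lt(abs(fit$theta - 500), 25)

  # strongly truncated controls: the underlying normal is still recovered
  ctrl_tr <- rnorm(40000, 5, 10); ctrl_tr <- ctrl_tr[ctrl_tr > 0][1:10000]
  fit2 <- fit_normexp(observed, ctrl_tr)
  expect_lt(abs(fit2$mu - 5), 1.5)
  expect_lt(abs(fit2$sigma - 10), 1.5)

  # observed indistinguishable from background: theta floored with warning
  expect_warning(fit3 <- fit_normexp(controls, controls), "floor")
  expect_equal(fit3$theta, 1)
  expect_error(fit_normexp(observed, controls[1:5]), "10")
})

test_that("normexp correction matches the quadrature posterior mean", {
  grid <- expand.grid(x = c(-50, 0, 50, 90, 100, 120, 200, 1000),
                      mu = c(0, 100), sigma = c(1, 10, 30),
                      theta = c(50, 500))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    got <- normexp_correct(g$x, list(mu = g$mu, sigma = g$sigma, theta = g$theta))
    want <- quadrature_normexp(g$x, g$mu, g$sigma, g$theta)
    expect_equal(got, want, tolerance = 1e-6,
                 label = sprintf("E[S|x=%g,mu=%g,sigma=%g,theta=%g]",
                                 g$x, g$mu, g$sigma, g$theta))
  }
})

test_that("normexp correction is positive, monotone, and x - mu in the low-noise limit", {
  par <- list(mu = 100, sigma = 10, theta = 300)
  x <- seq(-200, 2000, by = 10)
  y <- normexp_correct(x, par)
  expect_true(all(y > 0))
  expect_true(all(diff(y) > 0))
  # sigma -> 0 with x > mu: corrected -> x - mu
  par0 <- list(mu = 100, sigma = 1e-4, theta = 300)
  expect_equal(normexp_correct(500, par0), 400, tolerance = 1e-3)
})

test_that("quantile normalization equalizes column distributions and keeps ranks", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  rownames(m) <- c("p1", "p2", "p3")
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, "b"]), c(2.5, 3.5, 4.5))

  # identical columns are a fixed point
  m2 <- cbind(x = c(5, 1, 9), y = c(5, 1, 9))
  expect_equal(quantile_normalize(m2), m2, ignore_attr = FALSE)

  # property: all columns share a multiset; within-column ranks preserved
  set.seed(4)
  m3 <- matrix(rexp(500 * 5), 500, 5,
               dimnames = list(NULL, paste0("s", 1:5)))
  qn3 <- quantile_normalize(m3)
  ref <- sort(qn3[, 1])
  for (j in 2:5) expect_equal(sort(qn3[, j]), ref)
  for (j in 1:5) expect_equal(cor(m3[, j], qn3[, j], method = "spearman"), 1)
})

test_that("beta and M-value transforms follow their formulas", {
  expect_equal(compute_beta(1000, 1000, 100), 1000 / 2100)
  expect_equal(compute_beta(0, 500, 100), 0)
  expect_equal(compute_beta(500, 0, 0), 1)
  expect_error(compute_beta(0, 0, 0), "undefined")

  expect_equal(beta_to_mvalue(0.5), 0)
  expect_equal(beta_to_mvalue(0.8), 2)
  expect_equal(beta_to_mvalue(0.2), -2)
  # clamping makes the transform total at the boundary
  expect_true(is.finite(beta_to_mvalue(0)) && is.finite(beta_to_mvalue(1)))
  expect_equal(beta_to_mvalue(0), -beta_to_mvalue(1))
})
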