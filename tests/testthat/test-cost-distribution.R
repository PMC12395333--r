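test_that("outlier filtering removes records strictly beyond the bound", {
  r <- cost_records(c(0.1, 0.3, -0.26, 0.25, -0.25))
  kept <- filter_outliers(r)
  expect_equal(kept$cost, c(0.1, 0.25, -0.25))  # bound itself retained
  expect_equal(attr(kept, "n_removed"), 2)
  empty <- filter_outliers(cost_records(numeric(0)))
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "n_removed"), 0)
})

test_that("mixture density combines a positive exponential and a zero-centred Gaussian", {
  m <- cost_mixture_model(w = 0.7, rate = 12.8, sigma = 0.05)
  # no negative support for the exponential part
  m1 <- cost_mixture_model(w = 0.999999, rate = 12.8, sigma = 0.05)
  expect_lt(mixture_density(m1, -0.1), 1e-4)
  m0 <- cost_mixture_model(w = 1e-9, rate = 12.8, sigma = 0.05)
  expect_equal(mixture_density(m0, 0), 1 / (0.05 * sqrt(2 * pi)),
               tolerance = 1e-6)
  # density integrates to one (quadrature oracle)
  int <- stats::integrate(function(x) mixture_density(m, x), -1, 2,
                          subdivisions = 1000, rel.tol = 1e-9)
  expect_equal(int$value, 1, tolerance = 1e-6)
})

test_that("maximum likelihood recovers the mixture parameters", {
  g <- gen_cost_records(n = 5000, w = 0.7, rate = 12.8, sigma = 0.05,
                        seed = 101)
  fit <- fit_mixture(g$records)
  expect_lt(abs(fit$w - 0.7) / 0.7, 0.10)
  expect_lt(abs(fit$rate - 12.8) / 12.8, 0.10)
  expect_lt(abs(fit$sigma - 0.05) / 0.05, 0.10)
  # agreement with an independent EM fit of the same data
  em <- oracle_em_mixture(g$records$cost)
  expect_equal(fit$w, em$w, tolerance = 1e-3)
  expect_equal(fit$rate, em$rate, tolerance = 1e-3)
  expect_equal(fit$sigma, em$sigma, tolerance = 1e-3)
})

test_that("an all-positive exponential sample drives the weight toward one", {
  set.seed(55)
  x <- rexp(500, rate = 15)
  fit <- fit_mixture(x)
  expect_gte(fit$w, 0.9)
})

test_that("degenerate or undersized samples are rejected", {
  expect_error(fit_mixture(rexp(10, 10)),
               class = "pnecres_insufficient_records")
  expect_error(fit_mixture(-abs(rnorm(50, 0, 0.05))),
               class = "pnecres_input_error")
})

test_that("fitting is invariant to record order and dataset duplication", {
  g <- gen_cost_records(n = 200, seed = 17)
  x <- g$records$cost
  f1 <- fit_mixture(x)
  f2 <- fit_mixture(rev(x))
  f3 <- fit_mixture(c(x, x))
  expect_equal(f1$rate, f2$rate, tolerance = 1e-6)
  expect_equal(f1$rate, f3$rate, tolerance = 1e-4)
  expect_equal(f1$w, f3$w, tolerance = 1e-4)
})

test_that("quantile and CDF of the exponential component invert exactly", {
  rate <- 12.8
  for (p in c(0.001, 0.01, 0.05, 0.25, 0.5, 0.9, 0.999)) {
    q <- cost_quantile(rate, p)
    expect_equal(stats::pexp(q, rate), p, tolerance = 1e-12)
  }
  expect_equal(cost_quantile(rate, 1e-12), 0, tolerance = 1e-10)
  expect_error(cost_quantile(rate, 1), class = "pnecres_input_error")
  # quantile ratios are free of the fitted rate
  expect_equal(cost_quantile(rate, 0.5) / cost_quantile(rate, 0.05),
               log(0.5) / log(0.95))
  expect_equal(log(0.5) / log(0.95), 13.51, tolerance = 1e-3)
  # rate calibration inverts the quantile function
  expect_equal(cost_quantile(rate_from_quantile(0.05, 0.0040), 0.05), 0.0040)
})

test_that("rate estimation error shrinks with sample size", {
  sizes <- c(100, 1000, 5000)
  med_err <- vapply(sizes, function(n) {
    errs <- vapply(1:5, function(s) {
      g <- gen_cost_records(n = n, w = 0.7, rate = 12.8, sigma = 0.05,
                            seed = 1000 + s)
      abs(fit_mixture(g$records)$rate - 12.8)
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})

test_that("bootstrap intervals are seeded, bounded and bracket the estimate", {
  g <- gen_cost_records(n = 300, seed = 23)
  ci <- bootstrap_ci(g$records, p = 0.05, B = 200, seed = 9)
  expect_lt(ci$lower, ci$estimate)
  expect_gt(ci$upper, ci$estimate)
  ci2 <- bootstrap_ci(g$records, p = 0.05, B = 200, seed = 9)
  expect_identical(ci$replicates, ci2$replicates)  # reproducible
  expect_error(bootstrap_ci(g$records, 0.05, B = 0),
               class = "pnecres_input_error")
})

test_that("profile-likelihood CI matches the Wald interval on large samples", {
  g <- gen_cost_records(n = 3000, w = 0.7, rate = 12.8, sigma = 0.05,
                        seed = 31)
  prof <- profile_ci_rate(g$records)
  expect_false(prof$one_sided)
  # Wald CI from the numerically profiled curvature at the optimum
  x <- g$records$cost
  fit <- fit_mixture(x)
  h <- 1e-4
  nll <- function(r) pnecres:::mixture_nll(
    c(stats::qlogis(fit$w), log(r), log(fit$sigma)), x)
  # second derivative wrt rate via log-scale finite differences
  lr <- log(fit$rate)
  d2 <- (nll(exp(lr + h)) - 2 * nll(exp(lr)) + nll(exp(lr - h))) / h^2
  se_log <- 1 / sqrt(d2)
  wald <- exp(lr + c(-1, 1) * 1.96 * se_log)
  expect_equal(prof$lower, wald[1], tolerance = 0.10)
  expect_equal(prof$upper, wald[2], tolerance = 0.10)
})

test_that("the rate interval is scale-equivariant", {
  g <- gen_cost_records(n = 400, seed = 37)
  a <- profile_ci_rate(g$records$cost)
  b <- profile_ci_rate(g$records$cost * 2)
  expect_equal(b$rate, a$rate / 2, tolerance = 1e-4)
  expect_equal(b$lower, a$lower / 2, tolerance = 1e-3)
  expect_equal(b$upper, a$upper / 2, tolerance = 1e-3)
})

test_that("plasmid and chromosomal cost distributions are compared by rank sum", {
  vals <- (1:20) / 100
  same <- cost_records(c(vals, vals),
                       localization = rep(c("plasmid", "chromosome"),
                                          each = 20))
  res_same <- suppressWarnings(compare_localizations(same))
  expect_gt(res_same$p_value, 0.95)
  expect_equal(res_same$direction, 0)
  # exact small-sample p-value against brute-force enumeration
  small <- cost_records(c(1, 2, 3, 4, 5, 6) / 100,
                        localization = rep(c("plasmid", "chromosome"),
                                           each = 3))
  res_small <- compare_localizations(small)
  expect_equal(res_small$p_value, 0.1)
  expect_equal(res_small$p_value,
               oracle_wilcox_exact(c(1, 2, 3) / 100, c(4, 5, 6) / 100))
  expect_equal(res_small$direction, -1)
  # clearly shifted groups
  set.seed(71)
  shifted <- cost_records(c(rnorm(100, 0.02, 0.01), rnorm(100, 0.07, 0.01)),
                          localization = rep(c("plasmid", "chromosome"),
                                             each = 100))
  expect_lt(compare_localizations(shifted)$p_value, 1e-3)
  # single group is rejected
  expect_error(compare_localizations(cost_records(rnorm(5, 0.05, 0.01))),
               class = "pnecres_input_error")
})
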