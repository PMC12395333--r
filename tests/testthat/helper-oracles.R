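# Independent oracles used to cross-check package implementations.

# Closed-form MSC for the power-law dose-response family: equating
# mu0*(1-c^k/mic^k) and mu0*(1-cost)*(1-c^k/(f*mic)^k) gives
# c = mic * (cost / (1 - (1-cost)/f^k))^(1/k).
oracle_msc_power <- function(cost, f, shape, mic_sus = 1) {
  mic_sus * (cost / (1 - (1 - cost) / f^shape))^(1 / shape)
}

# EM algorithm for the exponential+Gaussian mixture (zero-centred
# Gaussian); independent of the package's direct-MLE route.
oracle_em_mixture <- function(x, w = 0.5, rate = 10, sigma = 0.05,
                              iters = 500L, tol = 1e-10) {
  for (i in seq_len(iters)) {
    fe <- ifelse(x >= 0, stats::dexp(x, rate), 0)
    fn <- stats::dnorm(x, 0, sigma)
    r <- w * fe / (w * fe + (1 - w) * fn)
    w_new <- mean(r)
    rate_new <- sum(r) / sum(r * x)
    sigma_new <- sqrt(sum((1 - r) * x^2) / sum(1 - r))
    delta <- max(abs(c(w_new - w, rate_new - rate, sigma_new - sigma)))
    w <- w_new; rate <- rate_new; sigma <- sigma_new
    if (delta < tol) break
  }
  list(w = w, rate = rate, sigma = sigma)
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of the
# group assignments (small samples, no ties).
oracle_wilcox_exact <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  ranks <- rank(pooled)
  obs <- sum(ranks[seq_len(n)])
  idx <- utils::combn(length(pooled), n)
  stats <- apply(idx, 2, function(i) sum(rank(pooled)[i]))
  mu <- n * (length(pooled) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}

# Simulated logistic growth curve with lognormal measurement noise.
make_logistic_curve <- function(r, K = 1, od0 = 0.01, t_max = 10, dt = 0.5,
                                noise_sd = 0, replicate = "r1") {
  t <- seq(0, t_max, dt)
  od <- K * od0 * exp(r * t) / (K + od0 * (exp(r * t) - 1))
  if (noise_sd > 0) od <- od * exp(stats::rnorm(length(t), 0, noise_sd))
  growth_curve(t, od, replicate = replicate)
}

# Two-pass empirical MSC: factor-5 screening grid around the approximate
# MSC, then one refinement at factor 2 around the first estimate (the
# iterative grid-refinement workflow used with censored outcomes).
estimate_msc_refined <- function(cost, f, mic_sus = 1, noise_sd = 0,
                                 seed = 1L, ...) {
  g1 <- gen_competition_data(cost = cost, f = f, mic_sus = mic_sus,
                             noise_sd = noise_sd, seed = seed,
                             grid_factor = 5, ...)
  e1 <- empirical_msc(g1$observations)
  anchor <- if (e1$status == "interior-root") e1$msc else msc_approx(mic_sus, cost)
  grid <- anchor * 2^(-2:2)
  grid <- c(0, grid[grid < 0.95 * mic_sus])
  g2 <- gen_competition_data(cost = cost, f = f, mic_sus = mic_sus,
                             noise_sd = noise_sd, seed = seed + 1L,
                             concentrations = grid, ...)
  list(estimate = empirical_msc(g2$observations), truth = g1$truth)
}
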