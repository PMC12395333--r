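test_that("maximum exponential growth rate is recovered from OD600 series", {
  t <- seq(0, 8, 0.5)
  cv <- growth_curve(t, 0.01 * exp(0.6 * t))
  fit <- exponential_growth_rate(cv, window = 5)
  expect_equal(fit$rate, 0.6, tolerance = 1e-10)
  expect_gte(fit$r_squared, 0.999)
  # stationary culture: zero slope
  flat <- growth_curve(t, rep(0.01, length(t)))
  expect_equal(suppressWarnings(exponential_growth_rate(flat)$rate), 0)
  # below the detection floor everywhere: no growth signal
  dead <- growth_curve(t, rep(0.004, length(t)))
  expect_error(exponential_growth_rate(dead), class = "pnecres_no_growth")
  # invariance to rescaling all OD values
  cv2 <- growth_curve(t, 10 * 0.01 * exp(0.6 * t))
  expect_equal(exponential_growth_rate(cv2)$rate, fit$rate, tolerance = 1e-10)
})

test_that("logistic growth with noise yields unbiased intrinsic-rate estimates", {
  set.seed(7)
  rates <- replicate(30, {
    cv <- make_logistic_curve(r = 0.8, noise_sd = 0.01)
    suppressWarnings(exponential_growth_rate(cv, window = 5)$rate)
  })
  expect_lt(abs(mean(rates) - 0.8), 0.05)
})

test_that("resistance cost compares intrinsic growth rates", {
  expect_equal(cost_from_rates(0.95, 1.0), 0.05)
  expect_equal(cost_from_rates(1.0, 1.0), 0.0)
  expect_equal(cost_from_rates(1.05, 1.0), -0.05)
  expect_error(cost_from_rates(1, 0), class = "pnecres_input_error")
})

test_that("fitness ratio is the ratio of realized Malthusian parameters", {
  expect_equal(fitness_ratio(competition_observation(0, 1e3, 1e3, 1e7, 1e7)), 1.0)
  expect_equal(fitness_ratio(competition_observation(0, 1e3, 1e3, 1e5, 1e7)), 0.5)
  expect_equal(fitness_ratio(competition_observation(0, 1e3, 1e3, 1e7, 1e5)), 2.0)
  o1 <- competition_observation(0.1, 2e3, 3e3, 4e6, 5e6)
  # fold-change alternative; invariant to a common dilution factor applied
  # to both strains at one time point
  expect_equal(fitness_ratio(o1, method = "fold"),
               (4e6 / 2e3) / (5e6 / 3e3))
  o2 <- competition_observation(0.1, 2e3 * 50, 3e3 * 50, 4e6, 5e6)
  expect_equal(fitness_ratio(o2, method = "fold"),
               fitness_ratio(o1, method = "fold"))
  # Malthusian fr is invariant to rescaling one strain consistently at
  # both time points (counting in a different volume)
  o3 <- competition_observation(0.1, 2e3 * 10, 3e3, 4e6 * 10, 5e6)
  expect_equal(fitness_ratio(o3), fitness_ratio(o1))
  # susceptible strain unchanged: ratio undefined
  expect_error(fitness_ratio(competition_observation(0, 1e3, 1e3, 1e5, 1e3)),
               class = "pnecres_undefined_ratio")
})

test_that("empirical MSC is the fr = 1 root of the monotone spline", {
  # noise-free linear-model data on the documented screening grid
  g <- gen_competition_data(cost = 0.05, f = 100, mic_sus = 1, noise_sd = 0,
                            concentrations = c(0, 0.002, 0.01, 0.05, 0.25))
  est <- empirical_msc(g$observations)
  expect_equal(est$status, "interior-root")
  analytic <- msc_normalized(0.05, 100)  # 0.050505...
  expect_equal(est$msc, analytic, tolerance = 0.01)
  # root exactly at a knot
  knots <- pnecres:::msc_from_knots(c(0.04, 0.2, 1.0), c(1.5, 1.0, 0.5))
  expect_equal(knots$msc, 0.2)
  expect_equal(knots$status, "interior-root")
})

test_that("unbracketed fr = 1 crossings are censored, not errors", {
  mk <- function(conc, fr) {
    lapply(seq_along(conc), function(i)
      competition_observation(conc[i], 1e3, 1e3, 1e3 * exp(10 * fr[i]),
                              1e3 * exp(10)))
  }
  above <- empirical_msc(mk(c(0.01, 0.1, 1), c(1.2, 1.1, 1.05)))
  expect_equal(above$status, "above-highest-tested")
  expect_true(is.na(above$msc))
  below <- empirical_msc(mk(c(0.01, 0.1, 1), c(0.9, 0.7, 0.5)))
  expect_equal(below$status, "below-lowest-tested")
})

test_that("the monotone spline never overshoots the knot range", {
  g <- gen_competition_data(cost = 0.1, f = 50, noise_sd = 0, seed = 3)
  est <- empirical_msc(g$observations)
  x <- est$knots$concentration_mg_l
  y <- est$knots$fr
  spl <- stats::splinefun(x, y, method = "monoH.FC")
  for (i in seq_len(length(x) - 1)) {
    grid <- seq(x[i], x[i + 1], length.out = 50)
    vals <- spl(grid)
    expect_true(all(vals >= min(y[i], y[i + 1]) - 1e-12))
    expect_true(all(vals <= max(y[i], y[i + 1]) + 1e-12))
  }
})

test_that("replicate fitness ratios are aggregated, conflicting duplicates included", {
  obs <- c(
    gen_competition_data(cost = 0.05, f = 100, noise_sd = 0.05,
                         seed = 11)$observations,
    gen_competition_data(cost = 0.05, f = 100, noise_sd = 0.05,
                         seed = 12)$observations)
  est <- empirical_msc(obs)  # duplicated concentrations, no error
  expect_s3_class(est, "msc_estimate")
  expect_equal(anyDuplicated(est$knots$concentration_mg_l), 0L)
})

test_that("validation statistics summarize log10 mismatches", {
  s <- validation_stats(c(1, 2, 3), c(1, 2, 3))
  expect_equal(s$me, 0)
  expect_equal(s$mae, 0)
  expect_equal(s$fraction_within, 1)
  s2 <- validation_stats(c(2, 1), c(1, 2))
  expect_equal(s2$me, 0)
  expect_equal(s2$mae, log10(2))
  expect_equal(s2$fraction_within, 1)  # boundary inclusive at factor 2
  s3 <- validation_stats(10, 1)
  expect_equal(s3$me, 1)
  expect_equal(s3$mae, 1)
  expect_equal(s3$fraction_within, 0)
  expect_error(validation_stats(c(1, -1), c(1, 1)),
               class = "pnecres_input_error")
})
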