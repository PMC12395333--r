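# Analysis of growth-curve and competition-assay data: intrinsic growth
# rates, resistance costs, fitness ratios and empirical MSCs.

#' Growth curve of a single strain
#'
#' @param time_h strictly increasing time points, hours.
#' @param od600 optical densities (OD600), non-negative, same length.
#' @param replicate replicate identifier (default `"r1"`).
#' @return an object of class `growth_curve`.
#' @export
growth_curve <- function(time_h, od600, replicate = "r1") {
  if (!is.numeric(time_h) || !is.numeric(od600) ||
      length(time_h) != length(od600))
    stop_input("time_h and od600 must be numeric vectors of equal length")
  if (length(time_h) < 6L)
    stop_input("a growth curve needs at least 6 time points")
  if (any(diff(time_h) <= 0))
    stop_input("time points must be strictly increasing")
  if (any(od600 < 0)) stop_input("od600 must be non-negative")
  structure(list(time_h = time_h, od600 = od600,
                 replicate = as.character(replicate)),
            class = "growth_curve")
}

#' Maximum exponential growth rate from a growth curve
#'
#' Fits a linear model to natural-log OD600 against time within every
#' contiguous window of `window` points above the detection floor and
#' returns the maximum slope, i.e. the growth rate constant of the
#' exponential phase (per hour). A window with R-squared below `min_r2`
#' triggers a warning about a poorly defined exponential phase.
#'
#' @param curve a [growth_curve()].
#' @param window number of consecutive points per regression window (>= 3,
#'   default 5).
#' @param floor detection floor for OD600 (default 0.005); points at or
#'   below it are excluded.
#' @param min_r2 R-squared threshold for the quality warning (default 0.98).
#' @return list with `rate` (per hour), `r_squared`, and `window_time_h`
#'   (time range of the winning window).
#' @examples
#' cv <- growth_curve(seq(0, 8, 0.5), 0.01 * exp(0.6 * seq(0, 8, 0.5)))
#' exponential_growth_rate(cv)$rate  # 0.6
#' @export
exponential_growth_rate <- function(curve, window = 5L, floor = 0.005,
                                    min_r2 = 0.98) {
  stopifnot(inherits(curve, "growth_curve"))
  if (window < 3L) stop_input("window must be at least 3 points")
  ok <- curve$od600 > floor
  if (!any(ok))
    stop(errorCondition("all OD600 values at or below the detection floor: no growth",
                        class = c("pnecres_no_growth", "error")))
  # contiguous runs of usable points
  runs <- rle(ok)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  best <- NULL
  for (i in seq_along(runs$values)) {
    if (!runs$values[i] || runs$lengths[i] < window) next
    for (s in idx_start[i]:(idx_end[i] - window + 1L)) {
      sel <- s:(s + window - 1L)
      t <- curve$time_h[sel]
      y <- log(curve$od600[sel])
      fit <- stats::lm.fit(cbind(1, t), y)
      slope <- fit$coefficients[2L]
      ss_res <- sum(fit$residuals^2)
      ss_tot <- sum((y - mean(y))^2)
      r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
      if (is.null(best) || slope > best$rate)
        best <- list(rate = unname(slope), r_squared = r2,
                     window_time_h = range(t))
    }
  }
  if (is.null(best))
    stop(errorCondition("no contiguous window of points above the detection floor",
                        class = c("pnecres_no_growth", "error")))
  if (best$r_squared < min_r2)
    warning(sprintf("exponential phase poorly defined (R^2 = %.3f < %.2f)",
                    best$r_squared, min_r2))
  best
}

#' Resistance cost from intrinsic growth rates
#'
#' `cost = 1 - mu0_res/mu0_sus`, comparing the two strains at zero
#' antibiotic exposure. Negative values (fitness gain upon acquisition of
#' the determinant) are legitimate and occur in roughly 10% of literature
#' reports.
#'
#' @param mu0_res,mu0_sus intrinsic growth rates (per hour); `mu0_sus > 0`.
#' @return cost as a dimensionless fraction.
#' @examples
#' cost_from_rates(0.95, 1.0)  # 0.05
#' @export
cost_from_rates <- function(mu0_res, mu0_sus) {
  check_number(mu0_sus, "mu0_sus", lower = 0, strict_lower = TRUE)
  check_number(mu0_res, "mu0_res")
  1 - mu0_res / mu0_sus
}

#' One competition-assay observation
#'
#' Initial and final abundances (CFU/ml) of the resistant and susceptible
#' strain after one competition cycle at a given antibiotic concentration.
#'
#' @param concentration_mg_l tested concentration (mg/l; 0 = control).
#' @param a_res_0,a_sus_0,a_res_T,a_sus_T abundances, all > 0.
#' @param replicate replicate identifier.
#' @return an object of class `competition_observation`.
#' @export
competition_observation <- function(concentration_mg_l,
                                    a_res_0, a_sus_0, a_res_T, a_sus_T,
                                    replicate = "r1") {
  check_number(concentration_mg_l, "concentration_mg_l", lower = 0)
  for (nm in c("a_res_0", "a_sus_0", "a_res_T", "a_sus_T")) {
    check_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  }
  structure(list(concentration_mg_l = concentration_mg_l,
                 a_res_0 = a_res_0, a_sus_0 = a_sus_0,
                 a_res_T = a_res_T, a_sus_T = a_sus_T,
                 replicate = as.character(replicate)),
            class = "competition_observation")
}

#' Fitness ratio of the resistant over the susceptible strain
#'
#' Default (`method = "malthusian"`): ratio of realized Malthusian
#' parameters, `fr = ln(a_res_T/a_res_0) / ln(a_sus_T/a_sus_0)`. Under pure
#' exponential growth this equals `mu_res/mu_sus`, so `fr = 1` coincides
#' exactly with the growth-rate equality that defines the MSC.
#' `method = "fold"` gives the simple fold-change ratio
#' `(a_res_T/a_res_0) / (a_sus_T/a_sus_0)` instead.
#'
#' @param obs a [competition_observation()].
#' @param method `"malthusian"` (default) or `"fold"`.
#' @return dimensionless fitness ratio.
#' @examples
#' o <- competition_observation(0, 1e3, 1e3, 1e5, 1e7)
#' fitness_ratio(o)  # 0.5
#' @export
fitness_ratio <- function(obs, method = c("malthusian", "fold")) {
  stopifnot(inherits(obs, "competition_observation"))
  method <- match.arg(method)
  if (method == "fold")
    return((obs$a_res_T / obs$a_res_0) / (obs$a_sus_T / obs$a_sus_0))
  denom <- log(obs$a_sus_T / obs$a_sus_0)
  if (denom == 0)
    stop(errorCondition("susceptible strain did not change in abundance: fitness ratio undefined",
                        class = c("pnecres_undefined_ratio", "error")))
  log(obs$a_res_T / obs$a_res_0) / denom
}

#' Empirical MSC from competition data across a concentration gradient
#'
#' Aggregates replicate fitness ratios per concentration (geometric mean by
#' default), fits a monotone cubic Hermite spline (Fritsch-Carlson
#' tangents) through the (concentration, summary) knots, and returns the
#' concentration where the interpolated fitness ratio equals 1. If the
#' crossing is not bracketed by the tested concentrations the estimate is
#' censored: status `"above-highest-tested"` or `"below-lowest-tested"`,
#' classified by where the curve is heading. Censored outcomes are
#' first-class results so that concentration grids can be refined
#' iteratively.
#'
#' @param observations list of [competition_observation()] objects, or a
#'   data frame as returned by [read_competition_csv()].
#' @param aggregate `"geometric"` (default) or `"arithmetic"` replicate
#'   summary.
#' @param method fitness-ratio definition, see [fitness_ratio()].
#' @return an object of class `msc_estimate` with fields `msc` (mg/l or
#'   `NA` when censored), `status`, and `knots` (data frame of
#'   concentration and summary fr).
#' @export
empirical_msc <- function(observations,
                          aggregate = c("geometric", "arithmetic"),
                          method = c("malthusian", "fold")) {
  aggregate <- match.arg(aggregate)
  method <- match.arg(method)
  if (is.data.frame(observations)) observations <- as_observations(observations)
  fr <- vapply(observations, fitness_ratio, numeric(1), method = method)
  conc <- vapply(observations, function(o) o$concentration_mg_l, numeric(1))
  summarize <- function(v) {
    if (aggregate == "geometric") {
      if (any(v <= 0)) {
        warning("non-positive fitness ratios: falling back to arithmetic mean")
        mean(v)
      } else geometric_mean(v)
    } else mean(v)
  }
  agg <- vapply(split(fr, conc), summarize, numeric(1))
  x <- as.numeric(names(agg))
  o <- order(x)
  x <- x[o]
  y <- unname(agg[o])
  if (length(x) < 3L)
    stop_input("need fitness ratios at >= 3 distinct concentrations")
  msc_from_knots(x, y)
}

# Root of fr(c) = 1 on a monotone Hermite spline through the knots.
#' @noRd
msc_from_knots <- function(x, y) {
  knots <- data.frame(concentration_mg_l = x, fr = y)
  g <- y - 1
  hit <- which(g == 0)
  if (length(hit) > 0) {
    return(new_msc_estimate(x[hit[1L]], "interior-root", knots))
  }
  sgn <- sign(g)
  cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(cross) == 0) {
    # unbracketed: classify by whether the curve approaches 1 with growing c
    toward_one <- abs(g[length(g)]) < abs(g[1L])
    status <- if (toward_one) "above-highest-tested" else "below-lowest-tested"
    return(new_msc_estimate(NA_real_, status, knots))
  }
  spl <- stats::splinefun(x, y, method = "monoH.FC")
  i <- cross[1L]
  root <- stats::uniroot(function(c) spl(c) - 1, c(x[i], x[i + 1L]),
                         tol = .Machine$double.eps^0.5 * max(x))$root
  new_msc_estimate(root, "interior-root", knots)
}

#' @noRd
new_msc_estimate <- function(msc, status, knots) {
  structure(list(msc = msc, status = status, knots = knots),
            class = "msc_estimate")
}

#' @export
print.msc_estimate <- function(x, ...) {
  if (x$status == "interior-root") {
    cat(sprintf("Empirical MSC: %.4g mg/l (interior root, %d knots)\n",
                x$msc, nrow(x$knots)))
  } else {
    cat(sprintf("Empirical MSC censored: %s (%d knots)\n",
                x$status, nrow(x$knots)))
  }
  invisible(x)
}

#' Validation statistics for computed versus empirical MSCs
#'
#' Mismatches are expressed on the decadic log scale,
#' `log10(computed/empirical)`, to accommodate the wide range of MSCs.
#'
#' @param computed,empirical positive MSC vectors of equal length (mg/l).
#' @param k factor for the agreement fraction (default 2); a pair counts as
#'   agreeing when the ratio lies within `[1/k, k]`, boundaries included.
#' @return list with `me` (mean error), `mae` (mean absolute error), and
#'   `fraction_within` (share of pairs within factor `k`).
#' @examples
#' validation_stats(c(2, 1), c(1, 2))  # me 0, mae log10(2)
#' @export
validation_stats <- function(computed, empirical, k = 2) {
  if (length(computed) != length(empirical))
    stop_input("computed and empirical must have equal length")
  if (any(computed <= 0) || any(empirical <= 0))
    stop_input("MSC values must be positive")
  check_number(k, "k", lower = 1)
  d <- log10(computed / empirical)
  list(me = mean(d), mae = mean(abs(d)),
       fraction_within = mean(abs(d) <= log10(k) + 1e-12))
}
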