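# Closed-form MSC theory: growth-rate dose-response curves and the relation
# between the minimum selective concentration (MSC), the MIC and the cost of
# resistance.

#' Dose-response model of bacterial growth under antibiotic exposure
#'
#' Describes the growth rate of one strain as a function of antibiotic
#' concentration: `mu(c) = mu0 * max(0, 1 - (c/mic)^shape)`. With
#' `shape = 1` this is the linear consensus model used throughout the
#' framework; other exponents give a pluggable power-law family for convex
#' (`shape > 1`, response only near the MIC) or concave (`shape < 1`,
#' response already at very low doses) curves. Rates are clipped at zero
#' above the MIC: only the bacteriostatic regime is modelled, because
#' environmental concentrations beyond the MIC of susceptible strains are
#' rarely encountered.
#'
#' @param mu0 intrinsic growth rate at zero exposure (per hour, > 0).
#' @param mic minimum inhibitory concentration (mg/l, > 0).
#' @param shape dimensionless curvature exponent (> 0); 1 = linear.
#' @return an object of class `dose_response_model`.
#' @examples
#' m <- dose_response_model(mu0 = 1, mic = 2)
#' growth_rate(m, c(0, 1, 2, 5))
#' @export
dose_response_model <- function(mu0, mic, shape = 1) {
  check_number(mu0, "mu0", lower = 0, strict_lower = TRUE)
  check_number(mic, "mic", lower = 0, strict_lower = TRUE)
  check_number(shape, "shape", lower = 0, strict_lower = TRUE)
  structure(list(mu0 = mu0, mic = mic, shape = shape),
            class = "dose_response_model")
}

#' @export
print.dose_response_model <- function(x, ...) {
  cat(sprintf("Dose-response model: mu0 = %g /h, MIC = %g mg/l, shape = %g%s\n",
              x$mu0, x$mic, x$shape,
              if (x$shape == 1) " (linear)" else ""))
  invisible(x)
}

#' Growth rate at a given antibiotic concentration
#'
#' @param model a [dose_response_model()].
#' @param c_mg_l concentration(s), mg/l, non-negative.
#' @return growth rate(s) per hour; zero for concentrations at or above the
#'   MIC (bacteriostatic clipping).
#' @export
growth_rate <- function(model, c_mg_l) {
  stopifnot(inherits(model, "dose_response_model"))
  if (!is.numeric(c_mg_l) || any(!is.finite(c_mg_l)) || any(c_mg_l < 0))
    stop_input("concentrations must be finite and non-negative")
  model$mu0 * pmax(0, 1 - (c_mg_l / model$mic)^model$shape)
}

#' Susceptible/resistant strain pair
#'
#' Couples the dose-response models of an otherwise isogenic pair. The cost
#' of resistance is the fractional reduction of the intrinsic growth rate,
#' `cost = 1 - mu0_res/mu0_sus`; the resistance level `f = mic_res/mic_sus`
#' expresses the fold-increase of the MIC conferred by the determinant.
#'
#' @param sus,res [dose_response_model()] objects for the susceptible and
#'   resistant strain.
#' @return an object of class `strain_pair` with derived `cost` and `f`.
#' @examples
#' sp <- strain_pair(dose_response_model(1.0, 1), dose_response_model(0.95, 10))
#' sp$cost  # 0.05
#' sp$f     # 10
#' @export
strain_pair <- function(sus, res) {
  stopifnot(inherits(sus, "dose_response_model"),
            inherits(res, "dose_response_model"))
  cost <- 1 - res$mu0 / sus$mu0
  f <- res$mic / sus$mic
  if (f <= 0) stop_input("resistance level f must be positive")
  structure(list(sus = sus, res = res, cost = cost, f = f),
            class = "strain_pair")
}

#' @export
print.strain_pair <- function(x, ...) {
  cat(sprintf("Strain pair: cost = %.4g, resistance level f = %.4g\n",
              x$cost, x$f))
  invisible(x)
}

# Typed outcome for non-positive costs: without a fitness burden there is no
# concentration below which the susceptible strain wins, so no selective
# threshold exists and concentration control cannot prevent selection.
#' @noRd
stop_unselectable <- function(cost) {
  stop(errorCondition(
    sprintf(paste0("cost = %g is not positive: the resistant strain is never ",
                   "at a disadvantage, so no minimum selective concentration ",
                   "exists (unselectable by concentration control)"), cost),
    class = c("pnecres_unselectable", "pnecres_input_error", "error")))
}

#' Normalized minimum selective concentration (closed form)
#'
#' Under linear dose-response curves for both strains, equating the two
#' growth rates gives the MSC in units of the susceptible strain's MIC:
#' `MSC/MIC_sus = cost / (1 - (1 - cost)/f)`. For high-level resistance
#' (`f > 10`) this is numerically close to the cost itself, which motivates
#' the approximation `MSC = MIC_sus * cost` (see [msc_approx()]).
#'
#' @param cost resistance cost, fraction in (0, 1).
#' @param f resistance level `mic_res/mic_sus`, > 1.
#' @return dimensionless MSC/MIC_sus.
#' @examples
#' msc_normalized(0.05, 10)    # 0.05525
#' msc_normalized(0.05, 1e9)   # -> 0.05 in the high-resistance limit
#' @export
msc_normalized <- function(cost, f) {
  if (!is.numeric(cost) || length(cost) != 1L || !is.finite(cost))
    stop_input("cost must be a single finite number")
  if (cost <= 0) stop_unselectable(cost)
  if (cost >= 1) stop_input("cost must be < 1")
  check_number(f, "f", lower = 1, strict_lower = TRUE)
  cost / (1 - (1 - cost) / f)
}

#' Approximate MSC for high-level resistance
#'
#' `MSC = MIC_sus * cost`, valid when the resistant strain's MIC greatly
#' exceeds the susceptible strain's (`f > 10` covers most high-level
#' resistance determinants of clinical relevance, with a relative error
#' below about 12%).
#'
#' @param mic_sus MIC of the susceptible strain (mg/l, > 0).
#' @param cost resistance cost, fraction in (0, 1).
#' @return approximate MSC in the unit of `mic_sus`.
#' @examples
#' msc_approx(mic_sus = 8, cost = 0.004)  # 0.032
#' @export
msc_approx <- function(mic_sus, cost) {
  check_number(mic_sus, "mic_sus", lower = 0, strict_lower = TRUE)
  if (!is.numeric(cost) || length(cost) != 1L || !is.finite(cost))
    stop_input("cost must be a single finite number")
  if (cost <= 0) stop_unselectable(cost)
  if (cost >= 1) stop_input("cost must be < 1")
  mic_sus * cost
}

#' Numerical MSC by root finding on the growth-rate equality
#'
#' Locates the concentration where the two strains grow equally fast by
#' bisection on `growth_rate(res, c) - growth_rate(sus, c)` over
#' `(0, mic_sus)`. Works for any curve shape and serves as the independent
#' check of the closed form in [msc_normalized()].
#'
#' @param pair a [strain_pair()].
#' @param tol relative bracket tolerance (default 1e-12).
#' @return MSC in mg/l.
#' @export
msc_numeric <- function(pair, tol = 1e-12) {
  stopifnot(inherits(pair, "strain_pair"))
  if (pair$res$mu0 >= pair$sus$mu0) stop_unselectable(pair$cost)
  gap <- function(c) growth_rate(pair$res, c) - growth_rate(pair$sus, c)
  lo <- 0
  hi <- pair$sus$mic
  if (gap(lo) >= 0 || gap(hi) <= 0)
    stop(errorCondition("growth-rate curves do not cross in (0, mic_sus)",
                        class = c("pnecres_no_crossing", "error")))
  # plain bisection: monotone gap, relative bracket tolerance
  while ((hi - lo) > tol * max(lo, .Machine$double.xmin)) {
    mid <- (lo + hi) / 2
    if (mid <= lo || mid >= hi) break  # bracket at floating-point resolution
    if (gap(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Bias of the linear MSC formula under a nonlinear dose-response curve
#'
#' Ratio of the MSC obtained with a power-law exponent `shape` (applied to
#' both strains) to the MSC under the linear model, at identical `cost`,
#' `f` and `mic_sus`. Values above 1 mean the linear formula underestimates
#' the true MSC (convex curves, response only near the MIC); values below 1
#' mean it overestimates (concave curves). The sign and magnitude depend on
#' the antibiotic class, which is why a universal assessment factor cannot
#' absorb dose-response shape uncertainty.
#'
#' @inheritParams msc_normalized
#' @param shape curvature exponent applied to both strains (> 0).
#' @param mu0_sus,mic_sus intrinsic rate and MIC of the susceptible strain
#'   (the ratio is invariant to both; defaults 1).
#' @return dimensionless ratio `MSC(shape)/MSC(linear)`.
#' @examples
#' bias_under_shape(0.05, 100, shape = 1)  # 1
#' @export
bias_under_shape <- function(cost, f, shape, mu0_sus = 1, mic_sus = 1) {
  check_number(shape, "shape", lower = 0, strict_lower = TRUE)
  pair_with <- function(k) {
    strain_pair(dose_response_model(mu0_sus, mic_sus, shape = k),
                dose_response_model(mu0_sus * (1 - cost), mic_sus * f,
                                    shape = k))
  }
  if (!is.numeric(cost) || length(cost) != 1L || !is.finite(cost))
    stop_input("cost must be a single finite number")
  if (cost <= 0) stop_unselectable(cost)
  if (cost >= 1) stop_input("cost must be < 1")
  check_number(f, "f", lower = 1, strict_lower = TRUE)
  msc_numeric(pair_with(shape)) / msc_numeric(pair_with(1))
}
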