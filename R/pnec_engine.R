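# Combination of the lowest MIC with a resistance-cost quantile into a
# predicted no-effect concentration for resistance selection (PNEC_res).

#' Cost-based PNEC_res
#'
#' `PNEC_res = MIC_lowest * Q_p(cost)`: the lowest known MIC of the
#' antibiotic multiplied by a lower quantile of the resistance-cost
#' distribution. The quantile replaces the fixed assessment factor of
#' earlier frameworks with an ecologically interpretable quantity: at
#' `p = 0.05`, 5% of resistance determinants are cheap enough to still be
#' selected for at the threshold.
#'
#' @param mic_lowest lowest MIC (any concentration unit, > 0).
#' @param cost_quantile cost quantile `Q_p`, fraction in (0, 1).
#' @param ci optional length-2 confidence interval of the cost quantile;
#'   propagated by multiplying the interval ends.
#' @param p probability associated with the quantile (metadata).
#' @param antibiotic antibiotic name (metadata).
#' @param unit concentration unit label (default `"mg/l"`).
#' @param digits significant figures for the reported value (default 2 for
#'   cost-based results).
#' @return an object of class `pnec_result`.
#' @examples
#' compute_pnec(8, 0.004, unit = "ug/l")  # doxycycline: 0.032 ug/l
#' @export
compute_pnec <- function(mic_lowest, cost_quantile, ci = NULL, p = NA_real_,
                         antibiotic = NA_character_, unit = "mg/l",
                         digits = 2L) {
  check_number(mic_lowest, "mic_lowest", lower = 0, strict_lower = TRUE)
  check_number(cost_quantile, "cost_quantile", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  raw <- mic_lowest * cost_quantile
  ci_out <- if (!is.null(ci)) {
    if (length(ci) != 2L || any(ci <= 0)) stop_input("ci must be 2 positive numbers")
    sort(mic_lowest * ci)
  }
  structure(list(antibiotic = antibiotic,
                 mic_lowest = mic_lowest,
                 probability = p,
                 cost_quantile = cost_quantile,
                 cost_quantile_ci = if (is.null(ci)) NULL else sort(ci),
                 conversion_factor = conversion_factor(cost_quantile),
                 pnec_raw = raw,
                 pnec_ci = ci_out,
                 pnec_reported = round_reported(raw, digits = digits),
                 unit = unit,
                 method = "cost-based"),
            class = "pnec_result")
}

#' MIC-to-PNEC conversion factor implied by a cost quantile
#'
#' The reciprocal of the cost quantile, rounded to the nearest 10 when
#' large (the communicable "MIC_lowest/250" form) and to two significant
#' figures otherwise.
#'
#' @param cost_quantile cost quantile, fraction in (0, 1).
#' @return conversion factor (dimensionless).
#' @examples
#' conversion_factor(0.0040)  # 250
#' @export
conversion_factor <- function(cost_quantile) {
  check_number(cost_quantile, "cost_quantile", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  cf <- 1 / cost_quantile
  if (cf >= 20) round(cf / 10) * 10 else signif_half_up(cf, 2L)
}

#' Legacy PNEC_res with a fixed assessment factor
#'
#' The earlier convention: `PNEC_res = MIC_lowest / assessment_factor`
#' (factor 10 by default), followed by reporting rounding to one
#' significant figure.
#'
#' @inheritParams compute_pnec
#' @param assessment_factor fixed divisor (default 10).
#' @param digits significant figures for the reported value (default 1, the
#'   legacy convention).
#' @return an object of class `pnec_result` tagged
#'   `"fixed-assessment-factor"`.
#' @examples
#' legacy_pnec(16, unit = "ug/l")$pnec_reported  # 2
#' @export
legacy_pnec <- function(mic_lowest, assessment_factor = 10,
                        antibiotic = NA_character_, unit = "mg/l",
                        digits = 1L) {
  check_number(mic_lowest, "mic_lowest", lower = 0, strict_lower = TRUE)
  check_number(assessment_factor, "assessment_factor", lower = 0,
               strict_lower = TRUE)
  raw <- mic_lowest / assessment_factor
  structure(list(antibiotic = antibiotic,
                 mic_lowest = mic_lowest,
                 probability = NA_real_,
                 cost_quantile = NA_real_,
                 cost_quantile_ci = NULL,
                 conversion_factor = assessment_factor,
                 pnec_raw = raw,
                 pnec_ci = NULL,
                 pnec_reported = round_reported(raw, digits = digits),
                 unit = unit,
                 method = "fixed-assessment-factor"),
            class = "pnec_result")
}

#' Reporting rounding for PNEC values
#'
#' Default mode `"signif"` rounds half away from zero at `digits`
#' significant figures (legacy values are conventionally reported at one
#' significant figure, cost-based values at two so that e.g. 0.032
#' survives). Mode `"twofold"` snaps down to the two-fold test scale
#' instead.
#'
#' @param value positive concentration.
#' @param digits significant figures for mode `"signif"`.
#' @param mode `"signif"` (default) or `"twofold"`.
#' @return rounded value.
#' @examples
#' round_reported(1.6, digits = 1)   # 2
#' round_reported(0.032, digits = 2) # 0.032
#' @export
round_reported <- function(value, digits = 1L, mode = c("signif", "twofold")) {
  mode <- match.arg(mode)
  check_number(value, "value", lower = 0, strict_lower = TRUE)
  if (mode == "twofold") return(snap_to_scale(value))
  signif_half_up(value, digits = as.integer(digits))
}

#' @export
print.pnec_result <- function(x, ...) {
  lab <- if (is.na(x$antibiotic)) "" else paste0(" (", x$antibiotic, ")")
  if (x$method == "cost-based") {
    cat(sprintf(
      "PNEC_res%s: %g %s [raw %g], cost-based\n  MIC_lowest = %g %s, Q_%.2g(cost) = %.4g (conversion factor %g)\n",
      lab, x$pnec_reported, x$unit, x$pnec_raw, x$mic_lowest, x$unit,
      x$probability, x$cost_quantile, x$conversion_factor))
    if (!is.null(x$pnec_ci))
      cat(sprintf("  95%% CI: %.4g-%.4g %s\n",
                  x$pnec_ci[1L], x$pnec_ci[2L], x$unit))
  } else {
    cat(sprintf(
      "PNEC_res%s: %g %s [raw %g], fixed assessment factor %g\n  MIC_lowest = %g %s\n",
      lab, x$pnec_reported, x$unit, x$pnec_raw, x$conversion_factor,
      x$mic_lowest, x$unit))
  }
  invisible(x)
}

#' @export
as.data.frame.pnec_result <- function(x, ...) {
  data.frame(antibiotic = x$antibiotic,
             mic_lowest = x$mic_lowest,
             probability = x$probability,
             cost_quantile = x$cost_quantile,
             cost_quantile_lower = if (is.null(x$cost_quantile_ci)) NA_real_ else x$cost_quantile_ci[1L],
             cost_quantile_upper = if (is.null(x$cost_quantile_ci)) NA_real_ else x$cost_quantile_ci[2L],
             conversion_factor = x$conversion_factor,
             pnec_raw = x$pnec_raw,
             pnec_reported = x$pnec_reported,
             unit = x$unit,
             method = x$method,
             stringsAsFactors = FALSE)
}
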