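# Internal helpers shared across modules.

#' @noRd
stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("pnecres_input_error", "error")))
}

#' @noRd
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input(name, " must be a single finite number")
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_input(name, " = ", format(x), " is outside the admissible range")
  invisible(x)
}

#' Convert concentrations between mg/l and ug/l
#'
#' Concentrations are handled internally in mg/l; interfaces accept ug/l with
#' explicit conversion because MIC databases and regulatory thresholds mix
#' both units.
#'
#' @param x numeric vector of concentrations.
#' @param from,to source and target unit, `"mg/l"` or `"ug/l"`.
#' @return numeric vector in the target unit.
#' @examples
#' convert_conc(8, from = "ug/l", to = "mg/l")  # 0.008
#' @export
convert_conc <- function(x, from = c("mg/l", "ug/l"), to = c("mg/l", "ug/l")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (!is.numeric(x)) stop_input("x must be numeric")
  scale <- c("mg/l" = 1, "ug/l" = 1e-3)
  x * scale[[from]] / scale[[to]]
}

# Geometric mean; all values must be positive.
#' @noRd
geometric_mean <- function(x) exp(mean(log(x)))

# Round half away from zero at `digits` significant figures. base::signif()
# rounds half to even, which would turn the reporting convention into a
# platform detail.
#' @noRd
signif_half_up <- function(x, digits = 1L) {
  if (x == 0) return(0)
  mag <- floor(log10(abs(x))) - digits + 1L
  floor(abs(x) / 10^mag + 0.5) * 10^mag * sign(x)
}
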