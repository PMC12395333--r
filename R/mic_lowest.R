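# Extraction of a robust lowest MIC per antibiotic from species-wise MIC
# distribution tables on the two-fold dilution test scale, with a bias
# correction for limited species coverage.

#' Species-wise MIC distribution table
#'
#' Wide table of observation counts: one row per species, one column per
#' two-fold dilution bin (mg/l). This mirrors how EUCAST reports MIC
#' distributions.
#'
#' @param antibiotic antibiotic name.
#' @param counts integer matrix of observation counts, rows = species
#'   (rownames), columns = dilution bins; column names are concentrations
#'   in mg/l, strictly increasing, each double the previous.
#' @return an object of class `mic_distribution_table`.
#' @examples
#' m <- matrix(c(0, 40, 60, 50, 50, 0), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("sp1", "sp2"), c("0.25", "0.5", "1")))
#' mic_distribution_table("drugX", m)
#' @export
mic_distribution_table <- function(antibiotic, counts) {
  if (!is.matrix(counts) || is.null(rownames(counts)) ||
      is.null(colnames(counts)))
    stop_input("counts must be a matrix with species rownames and concentration colnames")
  conc <- as.numeric(colnames(counts))
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop_input("column names must be positive concentrations in mg/l")
  if (any(diff(conc) <= 0))
    stop_input("dilution bins must be strictly increasing")
  ratio <- conc[-1] / conc[-length(conc)]
  if (length(ratio) > 0 && any(abs(ratio - 2) > 1e-6))
    stop_input("dilution bins must double from one column to the next")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_input("counts must be non-negative integers")
  structure(list(antibiotic = as.character(antibiotic),
                 counts = counts, concentrations = conc),
            class = "mic_distribution_table")
}

#' @export
print.mic_distribution_table <- function(x, ...) {
  cat(sprintf("MIC distribution table: %s, %d species, bins %g..%g mg/l\n",
              x$antibiotic, nrow(x$counts),
              min(x$concentrations), max(x$concentrations)))
  invisible(x)
}

#' Robust minimum MIC of one species
#'
#' The minimum is not the lowest reported bin (single observations are
#' often artefacts) but the lowest bin carrying a non-negligible share of
#' the species' observations. Default rule: lowest bin whose count is at
#' least `max(2, 1% of the species' total)`. The rule is pluggable via
#' `rule`, a function of `(counts, concentrations)` returning a
#' concentration or `NA`.
#'
#' @param counts named numeric vector of observation counts; names are
#'   concentrations in mg/l.
#' @param rule optional replacement rule function.
#' @return robust minimum MIC in mg/l, or `NA` (with a warning) when no
#'   bin satisfies the rule.
#' @examples
#' robust_species_minimum(c("0.25" = 1, "0.5" = 40, "1" = 60))  # 0.5
#' @export
robust_species_minimum <- function(counts, rule = NULL) {
  conc <- as.numeric(names(counts))
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop_input("counts must be named by positive concentrations")
  o <- order(conc)
  conc <- conc[o]
  counts <- as.numeric(counts)[o]
  total <- sum(counts)
  if (total <= 0) {
    warning("species has no observations: skipped")
    return(NA_real_)
  }
  if (is.null(rule)) rule <- rule_min_count()
  rule(counts, conc)
}

#' Default robust-minimum rule
#'
#' Returns a rule accepting the lowest bin with count
#' `>= max(min_count, min_fraction * total)`.
#'
#' @param min_count absolute count floor (default 2).
#' @param min_fraction fraction of the species total (default 0.01).
#' @return a rule function for [robust_species_minimum()].
#' @export
rule_min_count <- function(min_count = 2, min_fraction = 0.01) {
  function(counts, concentrations) {
    thr <- max(min_count, min_fraction * sum(counts))
    ok <- which(counts >= thr)
    if (length(ok) == 0) {
      warning("no dilution bin meets the robust-minimum rule: species skipped")
      return(NA_real_)
    }
    concentrations[min(ok)]
  }
}

#' Preliminary lowest MIC of an antibiotic
#'
#' The minimum of the species-level robust minima; the most sensitive
#' species defines the preliminary estimate before any coverage
#' adjustment.
#'
#' @param table a [mic_distribution_table()].
#' @param rule robust-minimum rule, see [robust_species_minimum()].
#' @return an object of class `mic_lowest_result` with
#'   `preliminary_mic_lowest`, `adjusted_mic_lowest` (equal at this stage),
#'   `n_species` (species with any observations), `most_sensitive_species`
#'   and `adjustment_steps = 0`.
#' @export
preliminary_lowest <- function(table, rule = NULL) {
  stopifnot(inherits(table, "mic_distribution_table"))
  totals <- rowSums(table$counts)
  with_data <- totals > 0
  minima <- rep(NA_real_, nrow(table$counts))
  for (i in which(with_data)) {
    cnt <- table$counts[i, ]
    names(cnt) <- colnames(table$counts)
    minima[i] <- suppressWarnings(robust_species_minimum(cnt, rule = rule))
  }
  if (all(is.na(minima)))
    stop_input("no species passes the robust-minimum rule")
  best <- which.min(minima)
  structure(list(antibiotic = table$antibiotic,
                 preliminary_mic_lowest = minima[best],
                 adjusted_mic_lowest = minima[best],
                 n_species = sum(with_data),
                 most_sensitive_species = rownames(table$counts)[best],
                 adjustment_steps = 0L,
                 skipped_species = rownames(table$counts)[with_data & is.na(minima)]),
            class = "mic_lowest_result")
}

#' @export
print.mic_lowest_result <- function(x, ...) {
  cat(sprintf(
    "Lowest MIC for %s: preliminary %g mg/l, adjusted %g mg/l (%d species, %d step%s down; most sensitive: %s)\n",
    x$antibiotic, x$preliminary_mic_lowest, x$adjusted_mic_lowest,
    x$n_species, x$adjustment_steps, if (x$adjustment_steps == 1) "" else "s",
    x$most_sensitive_species))
  invisible(x)
}

# Continuous coverage model: expected positive bias of the preliminary
# estimate, in two-fold dilution steps, as a smooth decreasing function of
# the number of tested species. Calibrated so the continuous value is
# exactly 1.0 at n = 29 and 0.49 at n = 40 (rounding to 1 step and 0 steps
# respectively); rounding is half-up to keep the step count monotone.
#' @noRd
coverage_steps_exponential <- function(n_species,
                                       n_scale = 11 / log(1 / 0.49),
                                       s_max = exp(29 / (11 / log(1 / 0.49)))) {
  floor(s_max * exp(-n_species / n_scale) + 0.5)
}

#' Adjust a preliminary lowest MIC for limited species coverage
#'
#' With few tested species the preliminary lowest MIC is biased upward
#' (more testing tends to reveal more sensitive species). The adjustment
#' subtracts a number of two-fold dilution steps that shrinks with the
#' number of species, so results stay on the test scale.
#'
#' Models: `"exponential"` (default) uses a continuous decay
#' `steps(n) = round(s_max * exp(-n/n_scale))` calibrated so that
#' `steps(29) = 1` and `steps(n >= 40) = 0`; `"linear"` reproduces the
#' original discontinuous rule by scaling the value by `n/40` for `n < 40`
#' and snapping down to the two-fold scale.
#'
#' @param result a `mic_lowest_result` from [preliminary_lowest()], or a
#'   bare preliminary value in mg/l (then `n_species` is required).
#' @param n_species number of species with data (taken from `result` when
#'   it is a `mic_lowest_result`).
#' @param model `"exponential"` or `"linear"`.
#' @return the `mic_lowest_result` with `adjusted_mic_lowest` and
#'   `adjustment_steps` filled in.
#' @examples
#' coverage_adjustment(32, n_species = 29)$adjusted_mic_lowest  # 16
#' coverage_adjustment(8, n_species = 55)$adjusted_mic_lowest   # 8
#' @export
coverage_adjustment <- function(result, n_species = NULL,
                                model = c("exponential", "linear")) {
  model <- match.arg(model)
  if (!inherits(result, "mic_lowest_result")) {
    check_number(result, "preliminary value", lower = 0, strict_lower = TRUE)
    if (is.null(n_species)) stop_input("n_species is required")
    result <- structure(list(antibiotic = NA_character_,
                             preliminary_mic_lowest = result,
                             adjusted_mic_lowest = result,
                             n_species = as.integer(n_species),
                             most_sensitive_species = NA_character_,
                             adjustment_steps = 0L,
                             skipped_species = character(0)),
                        class = "mic_lowest_result")
  } else if (!is.null(n_species)) {
    result$n_species <- as.integer(n_species)
  }
  n <- result$n_species
  if (n < 1) stop_input("n_species must be at least 1")
  prelim <- result$preliminary_mic_lowest
  if (model == "exponential") {
    steps <- coverage_steps_exponential(n)
    adjusted <- prelim / 2^steps
  } else {
    adjusted <- if (n >= 40) prelim else snap_to_scale(prelim * n / 40)
    steps <- round(log2(prelim / adjusted))
  }
  result$adjusted_mic_lowest <- adjusted
  result$adjustment_steps <- as.integer(steps)
  result
}

#' Snap a concentration down to the two-fold test scale
#'
#' Rounds down to the nearest `2^k` mg/l (integer `k`, possibly negative),
#' the resolution at which MICs are reported.
#'
#' @param value positive concentration, mg/l.
#' @return largest power of two not exceeding `value`.
#' @examples
#' snap_to_scale(0.3)  # 0.25
#' snap_to_scale(1.6)  # 1
#' @export
snap_to_scale <- function(value) {
  check_number(value, "value", lower = 0, strict_lower = TRUE)
  2^floor(log2(value) + 1e-9)
}
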