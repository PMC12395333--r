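# End-to-end PNEC_res pipeline: MIC table(s) + cost database -> PNEC table.

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run so that all defaults are
#' serialized into the output for provenance.
#'
#' @param probability tolerated selection probability `p` (default 0.05).
#' @param localization cost-record filter (default `"plasmid"`, the
#'   regulatory focus; `"chromosome"` or `"all"`).
#' @param outlier_threshold absolute-cost outlier bound (default 0.25).
#' @param bootstrap_B bootstrap replicates for the quantile CI (default
#'   1000; 0 disables the CI).
#' @param seed integer seed driving all randomness of the run.
#' @param adjustment_model species-coverage model, see
#'   [coverage_adjustment()].
#' @param rounding_digits significant figures for reported PNECs.
#' @param unit concentration unit label of the MIC inputs.
#' @param method `"cost-based"` (default) or `"legacy"` (fixed assessment
#'   factor of 10).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(probability = 0.05, localization = "plasmid",
                            outlier_threshold = 0.25, bootstrap_B = 1000L,
                            seed = 1L, adjustment_model = "exponential",
                            rounding_digits = 2L, unit = "mg/l",
                            method = c("cost-based", "legacy")) {
  structure(list(probability = probability, localization = localization,
                 outlier_threshold = outlier_threshold,
                 bootstrap_B = as.integer(bootstrap_B),
                 seed = as.integer(seed),
                 adjustment_model = adjustment_model,
                 rounding_digits = as.integer(rounding_digits),
                 unit = unit, method = match.arg(method)),
            class = "pipeline_config")
}

#' Run the full PNEC_res pipeline
#'
#' For each antibiotic: extract the coverage-adjusted lowest MIC from its
#' distribution table; filter the cost database (localization, outliers);
#' fit the exponential+Gaussian mixture; evaluate the cost quantile (with
#' bootstrap CI when enabled); multiply the two into PNEC_res. A failing
#' antibiotic is skipped with a logged reason, never aborting the batch.
#'
#' @param mic_tables a [mic_distribution_table()], a list of them, or a
#'   path readable by [read_mic_table()].
#' @param costs a [cost_records()] table, numeric cost vector, or a CSV
#'   path readable by [read_cost_csv()]. Ignored in legacy mode.
#' @param config a [pipeline_config()].
#' @return data frame of PNEC results (one row per antibiotic) with the
#'   configuration, fitted mixture and skip log attached as attributes
#'   `config`, `mixture` and `skipped`.
#' @export
run_pipeline <- function(mic_tables, costs = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(mic_tables)) mic_tables <- read_mic_table(mic_tables)
  if (inherits(mic_tables, "mic_distribution_table"))
    mic_tables <- list(mic_tables)

  mixture <- NULL
  q <- ci <- NULL
  if (config$method == "cost-based") {
    if (is.null(costs)) stop_input("cost-based mode requires a cost database")
    if (is.character(costs)) costs <- read_cost_csv(costs)
    if (is.numeric(costs)) costs <- cost_records(costs)
    if (nrow(costs) == 0) stop_input("cost database is empty")
    if (config$localization != "all")
      costs <- costs[costs$localization == config$localization, , drop = FALSE]
    costs <- filter_outliers(costs, config$outlier_threshold)
    if (nrow(costs) == 0)
      stop_input("no cost records left after filtering")
    mixture <- fit_mixture(costs)
    q <- cost_quantile(mixture, config$probability)
    if (config$bootstrap_B > 0) {
      bs <- bootstrap_ci(costs, config$probability, B = config$bootstrap_B,
                         seed = config$seed)
      ci <- c(bs$lower, bs$upper)
    }
  }

  rows <- list()
  skipped <- character(0)
  for (tbl in mic_tables) {
    res <- tryCatch({
      ml <- coverage_adjustment(preliminary_lowest(tbl),
                                model = config$adjustment_model)
      if (config$method == "legacy") {
        legacy_pnec(ml$adjusted_mic_lowest, antibiotic = tbl$antibiotic,
                    unit = config$unit)
      } else {
        compute_pnec(ml$adjusted_mic_lowest, q, ci = ci,
                     p = config$probability, antibiotic = tbl$antibiotic,
                     unit = config$unit, digits = config$rounding_digits)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- c(skipped,
                   sprintf("%s: %s", tbl$antibiotic, conditionMessage(res)))
    } else {
      rows[[length(rows) + 1L]] <- as.data.frame(res)
    }
  }
  if (length(rows) == 0)
    stop_input("no antibiotic could be processed; skip log: ",
               paste(skipped, collapse = "; "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- unclass(config)
  attr(out, "mixture") <- mixture
  attr(out, "skipped") <- skipped
  out
}
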