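# Readers and writers for the plain-text interchange formats: competition
# and growth-curve CSVs, EUCAST-style MIC tables (wide and long), and cost
# databases.

#' @noRd
require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop_input(what, " is missing required column(s): ",
               paste(missing, collapse = ", "))
  invisible(df)
}

#' Read a competition-assay CSV
#'
#' Expected columns: `concentration_mg_l`, `replicate`, `a_res_t0`,
#' `a_sus_t0`, `a_res_t24`, `a_sus_t24`. The `_mg_l` suffix is the unit
#' contract; concentrations in other units must be converted on export.
#'
#' @param path CSV file path.
#' @return data frame with the validated columns.
#' @export
read_competition_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("concentration_mg_l", "replicate", "a_res_t0",
                        "a_sus_t0", "a_res_t24", "a_sus_t24"),
                  "competition CSV")
  if (any(df$concentration_mg_l < 0))
    stop_input("concentrations must be non-negative")
  ab <- c(df$a_res_t0, df$a_sus_t0, df$a_res_t24, df$a_sus_t24)
  if (any(!is.finite(ab)) || any(ab <= 0))
    stop_input("abundances must be positive")
  df
}

#' @noRd
as_observations <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    competition_observation(df$concentration_mg_l[i],
                            df$a_res_t0[i], df$a_sus_t0[i],
                            df$a_res_t24[i], df$a_sus_t24[i],
                            replicate = df$replicate[i])
  })
}

#' Read a growth-curve CSV
#'
#' Expected columns: `time_h`, `replicate`, `od600`.
#'
#' @param path CSV file path.
#' @return named list of [growth_curve()] objects, one per replicate.
#' @export
read_growth_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("time_h", "replicate", "od600"), "growth CSV")
  lapply(split(df, df$replicate), function(d) {
    d <- d[order(d$time_h), ]
    growth_curve(d$time_h, d$od600, replicate = d$replicate[1L])
  })
}

#' Read an MIC distribution table (wide or long CSV)
#'
#' Wide dialect (EUCAST-style): first column `species`, remaining column
#' headers are concentrations in mg/l, cells are observation counts; one
#' antibiotic per file. Long dialect: columns `antibiotic`, `species`,
#' `mic_mg_l`, `count`. The dialect is auto-detected from the header.
#'
#' @param path CSV file path.
#' @param antibiotic antibiotic name for wide files (default: file name
#'   without extension); ignored for long files, which carry their own.
#' @return a [mic_distribution_table()] (wide input or single-antibiotic
#'   long input) or a named list of tables (multi-antibiotic long input).
#' @export
read_mic_table <- function(path, antibiotic = NULL) {
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  long <- all(c("antibiotic", "species", "mic_mg_l", "count") %in% header)
  if (long) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    tabs <- lapply(split(df, df$antibiotic), function(d) {
      conc <- sort(unique(d$mic_mg_l))
      species <- sort(unique(d$species))
      m <- matrix(0L, length(species), length(conc),
                  dimnames = list(species, format(conc, trim = TRUE,
                                                  scientific = FALSE)))
      for (i in seq_len(nrow(d)))
        m[d$species[i], format(d$mic_mg_l[i], trim = TRUE,
                               scientific = FALSE)] <- as.integer(d$count[i])
      mic_distribution_table(d$antibiotic[1L], m)
    })
    if (length(tabs) == 1L) return(tabs[[1L]])
    return(tabs)
  }
  if (header[1L] != "species")
    stop_input("wide MIC CSV must have 'species' as its first column")
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$species
  if (is.null(antibiotic))
    antibiotic <- sub("\\.[^.]*$", "", basename(path))
  mic_distribution_table(antibiotic, m)
}

#' Write an MIC distribution table as a wide CSV
#'
#' @param table a [mic_distribution_table()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_mic_table <- function(table, path) {
  stopifnot(inherits(table, "mic_distribution_table"))
  df <- data.frame(species = rownames(table$counts),
                   table$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a resistance-cost database CSV
#'
#' Expected columns: `cost`, `localization`; `genus`, `antibiotic` and
#' `source_doi` are carried along when present, as are any extra columns.
#'
#' @param path CSV file path.
#' @return a [cost_records()] table.
#' @export
read_cost_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("cost", "localization"), "cost database CSV")
  cost_records(df)
}
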