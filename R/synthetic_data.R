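# Synthetic-data generators with known ground truth. Every generator
# returns the data together with a `truth` list (and can write both to
# disk, data as CSV and truth as a JSON sidecar), so downstream checks
# never rely on magic numbers.

#' Generate synthetic resistance-cost records
#'
#' Draws costs from the exponential+Gaussian mixture
#' `w * Exp(rate) + (1 - w) * N(0, sigma)`. Defaults emulate the curated
#' literature collection: about 130 plasmid records whose exponential
#' component has a median near 5.4% of growth rate, producing roughly 10%
#' negative values. An optional chromosomal group is drawn with a larger
#' mean cost, mirroring the higher burden of chromosomal resistance.
#'
#' @param n number of plasmid records (default 130).
#' @param w,rate,sigma mixture truth (defaults 0.7, `log(2)/0.054`, 0.05).
#' @param n_chromosome optional number of chromosomal records (default 0).
#' @param chromosome_shift additive cost shift of the chromosomal
#'   exponential mean (default 0.05).
#' @param seed integer seed.
#' @return list with `records` (a [cost_records()] table) and `truth`.
#' @export
gen_cost_records <- function(n = 130L, w = 0.7, rate = log(2) / 0.054,
                             sigma = 0.05, n_chromosome = 0L,
                             chromosome_shift = 0.05, seed = 1L) {
  set.seed(as.integer(seed))
  draw <- function(m, rt) {
    comp <- stats::runif(m) < w
    ifelse(comp, stats::rexp(m, rate = rt), stats::rnorm(m, 0, sigma))
  }
  cost <- draw(n, rate)
  loc <- rep("plasmid", n)
  if (n_chromosome > 0) {
    rt_ch <- 1 / (1 / rate + chromosome_shift)
    cost <- c(cost, draw(n_chromosome, rt_ch))
    loc <- c(loc, rep("chromosome", n_chromosome))
  }
  records <- cost_records(cost, localization = loc,
                          genus = "Escherichia", antibiotic = "synthetic",
                          source_doi = "synthetic")
  list(records = records,
       truth = list(w = w, rate = rate, sigma = sigma, n = n,
                    n_chromosome = n_chromosome,
                    chromosome_shift = chromosome_shift, seed = seed))
}

#' Generate synthetic competition-assay data
#'
#' Simulates one 24-hour competition cycle at each concentration from the
#' linear (or power-law) dose-response truth of an isogenic strain pair.
#' Final abundances follow `a0 * exp(mu(c) * duration)` with multiplicative
#' lognormal counting noise. Concentrations default to the assay design
#' used in practice: a grid in multiples of `grid_factor` (default 5)
#' around the approximate MSC `mic_sus * cost`, capped below the
#' susceptible MIC, plus an antibiotic-free control.
#'
#' @param cost,f,mic_sus,shape strain-pair truth (defaults 0.05, 100,
#'   1 mg/l, linear).
#' @param mu0_sus susceptible intrinsic rate (default 0.8 per hour).
#' @param concentrations optional explicit concentration grid (mg/l).
#' @param grid_factor multiplicative spacing of the default grid.
#' @param n_replicates replicates per concentration (default 6).
#' @param duration_h competition period (default 24 h).
#' @param noise_sd lognormal counting-noise sd on the log scale (default
#'   0.1; 0 = noise-free).
#' @param a0 initial abundance of each strain (CFU/ml, default 5e5).
#' @param seed integer seed.
#' @return list with `observations` (list of
#'   [competition_observation()]), `data` (the same as a data frame) and
#'   `truth` (including the analytic `msc` from [msc_normalized()]).
#' @export
gen_competition_data <- function(cost = 0.05, f = 100, mic_sus = 1,
                                 shape = 1, mu0_sus = 0.8,
                                 concentrations = NULL, grid_factor = 5,
                                 n_replicates = 6L, duration_h = 24,
                                 noise_sd = 0.1, a0 = 5e5, seed = 1L) {
  set.seed(as.integer(seed))
  sus <- dose_response_model(mu0_sus, mic_sus, shape = shape)
  res <- dose_response_model(mu0_sus * (1 - cost), mic_sus * f, shape = shape)
  pair <- strain_pair(sus, res)
  msc_true <- if (cost > 0) msc_numeric(pair) else NA_real_
  if (is.null(concentrations)) {
    anchor <- if (cost > 0) msc_approx(mic_sus, cost) else 0.05 * mic_sus
    grid <- anchor * grid_factor^(-2:2)
    grid <- grid[grid < 0.9 * mic_sus]
    if (max(grid) < (if (is.na(msc_true)) anchor else msc_true))
      grid <- c(grid, 0.9 * mic_sus)
    concentrations <- c(0, grid)
  }
  obs <- list()
  rows <- list()
  for (cc in concentrations) {
    mu_r <- growth_rate(res, cc)
    mu_s <- growth_rate(sus, cc)
    for (r in seq_len(n_replicates)) {
      noise <- if (noise_sd > 0) stats::rnorm(4, 0, noise_sd) else numeric(4)
      ob <- competition_observation(
        concentration_mg_l = cc,
        a_res_0 = a0 * exp(noise[1L]),
        a_sus_0 = a0 * exp(noise[2L]),
        a_res_T = a0 * exp(mu_r * duration_h + noise[3L]),
        a_sus_T = a0 * exp(mu_s * duration_h + noise[4L]),
        replicate = paste0("r", r))
      obs[[length(obs) + 1L]] <- ob
      rows[[length(rows) + 1L]] <- data.frame(
        concentration_mg_l = cc, replicate = paste0("r", r),
        a_res_t0 = ob$a_res_0, a_sus_t0 = ob$a_sus_0,
        a_res_t24 = ob$a_res_T, a_sus_t24 = ob$a_sus_T,
        stringsAsFactors = FALSE)
    }
  }
  list(observations = obs,
       data = do.call(rbind, rows),
       truth = list(cost = cost, f = f, mic_sus = mic_sus, shape = shape,
                    mu0_sus = mu0_sus, msc = msc_true,
                    duration_h = duration_h, noise_sd = noise_sd,
                    n_replicates = n_replicates, seed = seed))
}

#' Generate a synthetic species-wise MIC distribution table
#'
#' Each species receives a modal dilution bin; its observation counts are
#' multinomial around that mode (isolates allocated to neighbouring
#' two-fold bins). The most sensitive species is given enough observations
#' at the designed floor bin to pass the default robust-minimum rule, so
#' the designed floor is the ground-truth preliminary lowest MIC.
#'
#' @param n_species number of species (default 55).
#' @param floor_mg_l designed lowest MIC (mg/l, on the two-fold scale;
#'   default 0.008).
#' @param n_bins number of dilution bins starting at `floor_mg_l`
#'   (default 12).
#' @param n_obs observations per species (default 200).
#' @param mode_spread sd (in bins) of species modal positions above the
#'   floor (default 2.5).
#' @param antibiotic name for the table (default `"synthetic"`).
#' @param seed integer seed.
#' @return list with `table` (a [mic_distribution_table()]) and `truth`.
#' @export
gen_mic_table <- function(n_species = 55L, floor_mg_l = 0.008,
                          n_bins = 12L, n_obs = 200L, mode_spread = 2.5,
                          antibiotic = "synthetic", seed = 1L) {
  set.seed(as.integer(seed))
  conc <- floor_mg_l * 2^(0:(n_bins - 1L))
  species <- sprintf("species_%02d", seq_len(n_species))
  counts <- matrix(0L, n_species, n_bins,
                   dimnames = list(species, format(conc, trim = TRUE,
                                                   scientific = FALSE)))
  # species 1 anchors the designed floor; the rest sit higher
  modes <- c(1L, pmin(n_bins,
                      2L + abs(round(stats::rnorm(n_species - 1L, 2,
                                                  mode_spread)))))
  for (i in seq_len(n_species)) {
    m <- modes[i]
    # triangular bin weights around the mode, truncated at the designed floor
    wgt <- pmax(0, 3 - abs(seq_len(n_bins) - m))
    if (i > 1L) wgt[seq_len(min(m, 2L) - 1L)] <- 0  # keep floor exclusive to species 1
    counts[i, ] <- as.integer(stats::rmultinom(1, n_obs, wgt / sum(wgt)))
  }
  # guarantee the floor bin passes the default rule for the anchor species
  if (counts[1L, 1L] < max(2, 0.01 * n_obs))
    counts[1L, 1L] <- as.integer(ceiling(max(2, 0.01 * n_obs)))
  tbl <- mic_distribution_table(antibiotic, counts)
  list(table = tbl,
       truth = list(floor_mg_l = floor_mg_l, n_species = n_species,
                    n_obs = n_obs, seed = seed))
}

#' Write generated data plus its ground-truth sidecar
#'
#' @param gen a list returned by one of the generators (must contain a
#'   `truth` element and one of `records`, `data` or `table`).
#' @param path CSV output path; the truth sidecar is written next to it
#'   with extension `.truth.json`.
#' @return invisibly, the sidecar path.
#' @export
write_with_truth <- function(gen, path) {
  if (!is.null(gen$records)) {
    utils::write.csv(gen$records, path, row.names = FALSE)
  } else if (!is.null(gen$data)) {
    utils::write.csv(gen$data, path, row.names = FALSE)
  } else if (!is.null(gen$table)) {
    write_mic_table(gen$table, path)
  } else stop_input("unrecognized generator output")
  sidecar <- sub("\\.csv$", "", path)
  sidecar <- paste0(sidecar, ".truth.json")
  jsonlite::write_json(gen$truth, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}
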