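test_that("robust species minimum rejects negligible low bins", {
  expect_equal(robust_species_minimum(c("0.25" = 1, "0.5" = 40, "1" = 60)), 0.5)
  expect_equal(robust_species_minimum(c("0.25" = 50, "0.5" = 50)), 0.25)
  # a single observation never passes the default absolute floor of 2
  expect_warning(val <- robust_species_minimum(c("2" = 1)), "skipped")
  expect_true(is.na(val))
  # the 1%-of-total branch dominates for very large samples
  cnt <- c("0.5" = 30, "1" = 5000)
  expect_equal(robust_species_minimum(cnt), 1)  # 30 < 1% of 5030? no: 30 < 50.3
  # pluggable rule: plain minimum of observed bins
  plain <- function(counts, conc) conc[min(which(counts > 0))]
  expect_equal(robust_species_minimum(c("0.25" = 1, "0.5" = 40), rule = plain),
               0.25)
})

test_that("the most sensitive species defines the preliminary lowest MIC", {
  mk <- function(minima) {
    bins <- 2^(0:8) * min(minima) / 2  # bins from one step below the lowest
    counts <- t(vapply(minima, function(m) {
      v <- integer(length(bins)); v[which(bins == m)] <- 100L; v
    }, integer(length(bins))))
    dimnames(counts) <- list(paste0("sp", seq_along(minima)),
                             format(bins, trim = TRUE, scientific = FALSE))
    mic_distribution_table("toy", counts)
  }
  r <- preliminary_lowest(mk(c(32, 64, 128)))
  expect_equal(r$preliminary_mic_lowest, 32)
  expect_equal(r$n_species, 3)
  expect_equal(r$most_sensitive_species, "sp1")
  expect_equal(preliminary_lowest(mk(0.5))$preliminary_mic_lowest, 0.5)
  expect_equal(preliminary_lowest(mk(c(4, 4)))$preliminary_mic_lowest, 4)
})

test_that("species-coverage adjustment honours its calibration anchors", {
  expect_equal(coverage_adjustment(32, n_species = 29)$adjusted_mic_lowest, 16)
  expect_equal(coverage_adjustment(32, n_species = 29)$adjustment_steps, 1L)
  expect_equal(coverage_adjustment(8, n_species = 55)$adjusted_mic_lowest, 8)
  expect_equal(coverage_adjustment(4, n_species = 40)$adjustment_steps, 0L)
  expect_equal(coverage_adjustment(4, n_species = 1000)$adjusted_mic_lowest, 4)
  # the original discontinuous linear rule as alternative
  lin <- coverage_adjustment(32, n_species = 29, model = "linear")
  expect_equal(lin$adjusted_mic_lowest, 16)
  expect_equal(coverage_adjustment(8, n_species = 55,
                                   model = "linear")$adjusted_mic_lowest, 8)
})

test_that("adjustment steps shrink monotonically with coverage and never raise the value", {
  steps <- vapply(1:120, function(n)
    coverage_adjustment(64, n_species = n)$adjustment_steps, integer(1))
  expect_true(all(diff(steps) <= 0))
  expect_true(all(steps >= 0))
  expect_true(all(steps[40:120] == 0))
  for (n in c(1, 5, 17, 29, 63)) {
    r <- coverage_adjustment(64, n_species = n)
    expect_lte(r$adjusted_mic_lowest, r$preliminary_mic_lowest)
    expect_equal(r$adjusted_mic_lowest == r$preliminary_mic_lowest,
                 r$adjustment_steps == 0L)
    # output stays on the two-fold scale spanned by the input
    expect_equal(log2(64 / r$adjusted_mic_lowest) %% 1, 0)
  }
})

test_that("adding a species never increases the preliminary lowest MIC", {
  set.seed(99)
  for (rep in 1:20) {
    g <- gen_mic_table(n_species = sample(5:30, 1), seed = rep)
    base <- preliminary_lowest(g$table)
    # append one more species with counts at a random bin
    counts <- g$table$counts
    extra <- integer(ncol(counts))
    extra[sample(ncol(counts), 1)] <- 50L
    counts2 <- rbind(counts, new_species = extra)
    grown <- preliminary_lowest(mic_distribution_table("syn", counts2))
    expect_lte(grown$preliminary_mic_lowest, base$preliminary_mic_lowest)
    expect_equal(grown$n_species, base$n_species + 1L)
  }
})

test_that("concentrations snap down to the two-fold test scale", {
  expect_equal(snap_to_scale(0.3), 0.25)
  expect_equal(snap_to_scale(8), 8)
  expect_equal(snap_to_scale(1.6), 1)
  expect_equal(snap_to_scale(0.002), 2^-9)
  expect_error(snap_to_scale(0), class = "pnecres_input_error")
})

test_that("MIC tables round-trip through CSV without changing results", {
  g <- gen_mic_table(n_species = 20, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_mic_table(g$table, path)
  back <- read_mic_table(path, antibiotic = g$table$antibiotic)
  expect_identical(back$counts, g$table$counts)
  expect_identical(preliminary_lowest(back), preliminary_lowest(g$table))
})

test_that("long-format MIC CSVs are auto-detected and equivalent", {
  g <- gen_mic_table(n_species = 6, seed = 8)
  wide <- g$table
  long <- do.call(rbind, lapply(rownames(wide$counts), function(sp) {
    data.frame(antibiotic = wide$antibiotic, species = sp,
               mic_mg_l = wide$concentrations,
               count = as.integer(wide$counts[sp, ]))
  }))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(long, path, row.names = FALSE)
  back <- read_mic_table(path)
  expect_equal(preliminary_lowest(back)$preliminary_mic_lowest,
               preliminary_lowest(wide)$preliminary_mic_lowest)
})
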