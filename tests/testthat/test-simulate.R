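test_that("generated cohort has the configured size, grid and labels", {
  cfg <- sim_config(seed = 3)
  sim <- generate_cohort(cfg)
  expect_length(sim$cohort$spectra, 58L)
  expect_equal(sum(sim$cohort$labels == "case"), 35L)
  expect_equal(sum(sim$cohort$labels == "control"), 23L)
  s <- sim$cohort$spectra[[1L]]
  expect_equal(range(s$mz), c(1000, 10000))
  expect_equal(diff(s$mz)[1], 1)
  # replicates multiply the spectrum count, not the sample count
  sim2 <- generate_cohort(small_sim_config(seed = 3, n_replicates = 3L))
  expect_length(sim2$cohort$spectra, 16L * 3L)
  expect_length(sim2$cohort$labels, 16L)
})

test_that("truth bookkeeping matches the configuration", {
  cfg <- small_sim_config(seed = 5)
  sim <- generate_cohort(cfg)
  expect_length(sim$truth$marker_centers, 2L)
  expect_length(sim$truth$background_centers, 20L)
  expect_equal(sim$truth$marker_fold_changes, c(0.6, 1.8),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_length(intersect(sim$truth$marker_centers,
                          sim$truth$background_centers), 0L)
  # all centers inside the mass range, pairwise separation >= 4 peak sd
  centers <- sort(c(sim$truth$marker_centers, sim$truth$background_centers))
  expect_true(all(centers > cfg$mass_range[1] & centers < cfg$mass_range[2]))
  sep_ok <- diff(centers) >= 4 * cfg$resolution_factor * centers[-1L]
  expect_true(all(sep_ok))
})

test_that("noiseless marker apex ratio equals the configured fold change exactly", {
  cfg <- small_sim_config(
    seed = 11, n_marker_peaks = 1L, marker_fold_changes = 2,
    noise_sd = 0, tic_scale_sd = 0, sample_peak_cv = 0, mz_jitter_sd = 0
  )
  sim <- generate_cohort(cfg)
  grid <- sim$cohort$spectra[[1L]]$mz
  baseline <- cfg$baseline_amplitude *
    exp(-(grid - cfg$mass_range[1]) / cfg$baseline_decay_Da)
  apex <- which.min(abs(grid - sim$truth$marker_centers))
  vals <- vapply(sim$cohort$spectra,
                 function(s) s$intensity[apex] - baseline[apex], numeric(1))
  labs <- vapply(sim$cohort$spectra, function(s) s$label, character(1))
  expect_equal(mean(vals[labs == "case"]) / mean(vals[labs == "control"]), 2,
               tolerance = 1e-9)
})

test_that("same configuration and seed reproduce bit-identical spectra", {
  a <- generate_cohort(small_sim_config(seed = 21))
  b <- generate_cohort(small_sim_config(seed = 21))
  expect_identical(
    lapply(a$cohort$spectra, `[[`, "intensity"),
    lapply(b$cohort$spectra, `[[`, "intensity")
  )
  expect_identical(a$truth, b$truth)
  d <- generate_cohort(small_sim_config(seed = 22))
  expect_false(identical(a$cohort$spectra[[1]]$intensity,
                         d$cohort$spectra[[1]]$intensity))
})

test_that("peak apexes sit within one grid step of truth centers when jitter is zero", {
  # sparse cohort so neighboring tails cannot displace an apex
  cfg <- sim_config(n_cases = 1, n_controls = 1, n_background_peaks = 8L,
                    n_marker_peaks = 0L, noise_sd = 0, mz_jitter_sd = 0,
                    seed = 7)
  sim <- generate_cohort(cfg)
  grid <- sim$cohort$spectra[[1L]]$mz
  y <- sim$cohort$spectra[[1L]]$intensity
  for (cc in sim$truth$background_centers) {
    win <- which(abs(grid - cc) <= 3 * cfg$resolution_factor * cc)
    apex <- grid[win][which.max(y[win])]
    expect_lte(abs(apex - cc), cfg$grid_step)
  }
})

test_that("technical replicates cluster by sample", {
  # replicates share their sample's scale factor, so the mean absolute
  # difference between replicates of one sample should be below the
  # between-sample distance in at least 9 of 10 seeds
  closer <- vapply(1:10, function(sd) {
    sim <- generate_cohort(small_sim_config(
      seed = sd, n_cases = 3L, n_controls = 3L, n_replicates = 2L,
      n_background_peaks = 15L, n_marker_peaks = 0L
    ))
    mat <- vapply(sim$cohort$spectra, `[[`, "intensity",
                  FUN.VALUE = numeric(3001))
    sids <- vapply(sim$cohort$spectra, `[[`, "sample_id",
                   FUN.VALUE = character(1))
    d <- as.matrix(stats::dist(t(mat), method = "manhattan")) / nrow(mat)
    same <- outer(sids, sids, "==") & upper.tri(d)
    diff_pair <- (!outer(sids, sids, "==")) & upper.tri(d)
    mean(d[same]) < mean(d[diff_pair])
  }, logical(1))
  expect_gte(sum(closer), 9L)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_cases = 0), "n_cases")
  expect_error(sim_config(grid_step = 0), "grid_step")
  expect_error(sim_config(mass_range = c(5000, 1000)), "mass_range")
  expect_error(sim_config(marker_fold_changes = c(1, -2)), "positive")
  expect_error(sim_config(n_background_peaks = 0, n_marker_peaks = 0),
               "at least one peak")
  expect_error(generate_cohort(list()), "sim_config")
})

test_that("cohorts round-trip through the text format", {
  sim <- generate_cohort(small_sim_config(
    seed = 13, n_cases = 2L, n_controls = 2L, n_background_peaks = 5L,
    n_marker_peaks = 1L, n_replicates = 2L
  ))
  dir <- withr::local_tempdir()
  files <- write_cohort(sim$cohort, dir, truth = sim$truth)
  expect_length(list.files(dir, pattern = "\\.txt$"), 8L)
  expect_true(file.exists(file.path(dir, "sample_sheet.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))

  back <- read_cohort(dir)
  expect_equal(length(back$spectra), length(sim$cohort$spectra))
  expect_equal(back$labels, sim$cohort$labels)
  for (i in seq_along(back$spectra)) {
    expect_equal(back$spectra[[i]]$intensity,
                 sim$cohort$spectra[[i]]$intensity, tolerance = 1e-7)
    expect_equal(back$spectra[[i]]$sample_id,
                 sim$cohort$spectra[[i]]$sample_id)
  }
  truth_back <- read_truth(file.path(dir, "truth.json"))
  expect_equal(truth_back$marker_centers, sim$truth$marker_centers,
               tolerance = 1e-12)
})

test_that("an empty cohort writes a header-only sample sheet", {
  dir <- withr::local_tempdir()
  write_cohort(new_cohort(list(), character(0)), dir)
  sheet <- readLines(file.path(dir, "sample_sheet.csv"))
  expect_equal(sheet, "spectrum_id,sample_id,replicate,label")
  expect_length(list.files(dir, pattern = "\\.txt$"), 0L)
})
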