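test_that("resampling interpolates linearly and preserves its own grid", {
  s <- const_spectrum(7)
  r <- resample_spectrum(s, seq(1100, 1900, by = 0.5))
  expect_true(all(r$intensity == 7))

  two <- new_spectrum(c(1000, 1002), c(0, 2), "s", "s")
  expect_equal(resample_spectrum(two, c(1000, 1001, 1002))$intensity,
               c(0, 1, 2))

  g <- gauss_spectrum(1500, 40, 5, mz = seq(1000, 2000))
  expect_identical(resample_spectrum(g, g$mz)$intensity, g$intensity)

  expect_error(resample_spectrum(two, c(999, 1000)), "outside")
  expect_error(resample_spectrum(two, c(1000, 1003)), "outside")
})

test_that("flat spectra produce their own baseline and zero after correction", {
  s <- const_spectrum(3)
  b <- estimate_baseline(s, 100)
  expect_equal(b$intensity, rep(3, length(s$mz)))
  corrected <- subtract_baseline(s, b)
  expect_true(all(corrected$intensity == 0))
})

test_that("baseline estimator recovers an exponential baseline within 5%", {
  mz <- seq(1000, 10000)
  truth <- 100 * exp(-(mz - 1000) / 3000)
  s <- new_spectrum(mz, truth, "b", "b")
  est <- estimate_baseline(s, 200)$intensity
  interior <- mz >= 1100 & mz <= 9900
  rel_err <- abs(est[interior] - truth[interior]) / truth[interior]
  expect_lt(max(rel_err), 0.05)
})

test_that("a peak on an exponential baseline is corrected to within 10% of its height", {
  mz <- seq(1000, 10000)
  s <- gauss_spectrum(5000, 50, 10, mz = mz, baseline_amp = 100,
                      baseline_decay = 3000)
  corrected <- subtract_baseline(s, estimate_baseline(s, 200))
  apex <- corrected$intensity[which(mz == 5000)]
  expect_lt(abs(apex - 50) / 50, 0.10)
})

test_that("baseline never exceeds the spectrum and subtraction clamps at zero", {
  set.seed(42)
  s <- gauss_spectrum(c(2000, 3500), c(30, 60), c(4, 7),
                      mz = seq(1000, 5000), baseline_amp = 50,
                      noise_sd = 1, seed = 42)
  b <- estimate_baseline(s, 200)
  expect_true(all(b$intensity <= s$intensity + 1e-12))
  corrected <- subtract_baseline(s, b)
  expect_true(all(corrected$intensity >= 0))

  over <- subtract_baseline(const_spectrum(5), rep(7, 1001))
  expect_true(all(over$intensity == 0))
  expect_equal(
    subtract_baseline(const_spectrum(10), rep(4, 1001))$intensity,
    rep(6, 1001)
  )
  expect_error(subtract_baseline(const_spectrum(5), rep(1, 10)), "grids")
  expect_error(estimate_baseline(const_spectrum(5), 0.5), "grid step")
  expect_error(estimate_baseline(const_spectrum(5), 5000), "span")
})

test_that("TIC normalization hits the target sum and is idempotent", {
  s <- new_spectrum(c(1000, 1001), c(1, 3), "s", "s")
  expect_equal(normalize_tic(s, 1)$intensity, c(0.25, 0.75))
  s3 <- new_spectrum(c(1000, 1001, 1002), c(2, 2, 4), "s", "s")
  expect_equal(normalize_tic(s3, 8)$intensity, c(2, 2, 4))

  once <- normalize_tic(s3, 1)
  expect_equal(normalize_tic(once, 1)$intensity, once$intensity)

  # property: sum equals target to 1e-9 relative for arbitrary positive input
  set.seed(1)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    sp <- new_spectrum(cumsum(runif(n, 0.5, 2)) + 1000,
                       runif(n, 0, 100), "s", "s")
    target <- runif(1, 0.1, 1000)
    expect_equal(sum(normalize_tic(sp, target)$intensity), target,
                 tolerance = 1e-9)
  }

  zero <- const_spectrum(0)
  expect_error(normalize_tic(zero), class = "maldirf_qc_error")
})

test_that("the mean spectrum is the pointwise average", {
  a <- new_spectrum(c(1000, 1001), c(0, 2), "a", "a", label = "case")
  b <- new_spectrum(c(1000, 1001), c(2, 4), "b", "b", label = "control")
  labels <- c(a = "case", b = "control")
  m <- mean_spectrum(new_cohort(list(a, b), labels))
  expect_equal(m$intensity, c(1, 3))
  one <- mean_spectrum(new_cohort(list(a), labels["a"]))
  expect_equal(one$intensity, a$intensity)
  three <- mean_spectrum(new_cohort(list(a, a, a), labels["a"]))
  expect_equal(three$intensity, a$intensity)
  mismatched <- new_spectrum(c(1000, 1002), c(1, 1), "c", "c")
  expect_error(
    mean_spectrum(new_cohort(list(a, mismatched),
                             c(labels, c = "case"))),
    "common"
  )
})

test_that("QC excludes degenerate spectra with a reason and refuses to drop everything", {
  good <- lapply(1:4, function(i) {
    gauss_spectrum(c(1500, 2500), c(30, 50), c(4, 5), mz = seq(1000, 3000),
                   noise_sd = 0.5, id = paste0("g", i), seed = i)
  })
  bad <- const_spectrum(0, mz = seq(1000, 3000), id = "zero")
  labels <- stats::setNames(rep(c("case", "control"), c(3, 2)),
                            c(paste0("g", 1:4), "zero"))
  cohort <- new_cohort(c(good, list(bad)), labels)
  res <- qc_filter(cohort)
  expect_equal(res$report$reason[res$report$spectrum_id == "zero"], "tic")
  expect_length(res$cohort$spectra, 4L)

  clean <- new_cohort(good, labels[1:4])
  expect_equal(sum(qc_filter(clean)$report$excluded), 0L)
  expect_error(qc_filter(clean, min_corr_to_mean = 1 + 1e-9),
               "all spectra excluded")
})

test_that("QC on a default synthetic cohort excludes nothing", {
  sim <- generate_cohort(small_sim_config(seed = 4))
  prep <- preprocess_cohort(sim$cohort)
  expect_equal(sum(prep$qc_report$excluded), 0L)
})

test_that("preprocessing preserves relative peak heights on noiseless data", {
  cfg <- small_sim_config(seed = 9, noise_sd = 0, mz_jitter_sd = 0,
                          baseline_amplitude = 0)
  sim <- generate_cohort(cfg)
  centers <- sort(c(sim$truth$marker_centers, sim$truth$background_centers))
  prep <- preprocess_cohort(sim$cohort, baseline_window_Da = 200)
  raw <- sim$cohort$spectra[[1L]]
  proc <- prep$cohort$spectra[[1L]]
  apex_idx <- vapply(centers, function(cc) which.min(abs(raw$mz - cc)),
                     integer(1))
  ratios_raw <- raw$intensity[apex_idx] / raw$intensity[apex_idx[1L]]
  ratios_proc <- proc$intensity[apex_idx] / proc$intensity[apex_idx[1L]]
  expect_equal(ratios_proc, ratios_raw, tolerance = 1e-6)
})
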