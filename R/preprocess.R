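# Preprocessing: resampling onto a common grid, rolling-minimum baseline
# estimation, baseline subtraction, total-ion-count normalization, mean
# spectrum, and quality-control filtering. The pipeline order is fixed:
# resample -> QC -> baseline -> normalize.

#' Resample a spectrum onto a new m/z grid by linear interpolation
#'
#' @param spectrum a `maldi_spectrum`.
#' @param grid ascending numeric m/z vector, contained in the spectrum's
#'   m/z span.
#' @return the resampled `maldi_spectrum`.
#' @export
resample_spectrum <- function(spectrum, grid) {
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("grid must be strictly ascending")
  span <- range(spectrum$mz)
  if (grid[1] < span[1] || grid[length(grid)] > span[2]) {
    stop(sprintf(
      "grid [%g, %g] outside spectrum span [%g, %g]",
      grid[1], grid[length(grid)], span[1], span[2]
    ))
  }
  y <- stats::approx(spectrum$mz, spectrum$intensity, xout = grid,
                     method = "linear")$y
  out <- spectrum
  out$mz <- grid
  out$intensity <- y
  out
}

#' Estimate a slowly varying baseline under a profile spectrum
#'
#' Rolling minimum over a `window_Da`-wide window, smoothed by a moving
#' average of the same width, then clamped so the estimate never exceeds the
#' spectrum pointwise. The window should be wide relative to the peaks
#' (several peak widths) and narrow relative to the baseline's decay.
#'
#' @param spectrum a `maldi_spectrum`.
#' @param window_Da window width in Da (default 200); must exceed the grid
#'   step and be at most the spectrum span.
#' @return a `maldi_spectrum` holding the baseline on the same grid.
#' @export
#' @examples
#' s <- new_spectrum(seq(1000, 2000), 100 * exp(-seq(1000, 2000) / 3000),
#'                   "s1", "p1")
#' b <- estimate_baseline(s, 200)
estimate_baseline <- function(spectrum, window_Da = 200) {
  step <- stats::median(diff(spectrum$mz))
  if (window_Da <= step) stop("window_Da must exceed the grid step")
  span <- diff(range(spectrum$mz))
  if (window_Da > span) {
    stop(sprintf("window_Da (%g) larger than spectrum span (%g)",
                 window_Da, span))
  }
  k <- window_points(window_Da, step)
  base <- moving_average(roll_min(spectrum$intensity, k), k)
  base <- pmin(base, spectrum$intensity)
  out <- spectrum
  out$intensity <- base
  out
}

#' Subtract a baseline, clamping at zero
#'
#' @param spectrum,baseline `maldi_spectrum` objects on the same grid
#'   (`baseline` may also be a bare numeric vector).
#' @return the corrected `maldi_spectrum` with non-negative intensities.
#' @export
subtract_baseline <- function(spectrum, baseline) {
  b <- if (inherits(baseline, "maldi_spectrum")) {
    if (length(baseline$mz) != length(spectrum$mz) ||
        !isTRUE(all.equal(baseline$mz, spectrum$mz, tolerance = 0))) {
      stop("spectrum and baseline are on different grids")
    }
    baseline$intensity
  } else {
    as.numeric(baseline)
  }
  if (length(b) != length(spectrum$intensity)) {
    stop("spectrum and baseline are on different grids")
  }
  out <- spectrum
  out$intensity <- pmax(spectrum$intensity - b, 0)
  out
}

#' Normalize a spectrum to a target total ion count
#'
#' Scales intensities so their sum equals `target_tic`. A spectrum whose
#' total ion count is not positive cannot be normalized and raises a
#' condition of class `maldirf_qc_error`, intended to be caught by
#' quality-control handling rather than passed through silently.
#'
#' @param spectrum a `maldi_spectrum`.
#' @param target_tic positive target sum (default 1).
#' @return the normalized `maldi_spectrum`.
#' @export
normalize_tic <- function(spectrum, target_tic = 1) {
  if (target_tic <= 0) stop("target_tic must be positive")
  tic <- sum(spectrum$intensity)
  if (tic <= 0) {
    stop(errorCondition(
      sprintf("spectrum %s has non-positive total ion count; exclude it in QC",
              spectrum$spectrum_id),
      class = "maldirf_qc_error"
    ))
  }
  out <- spectrum
  out$intensity <- spectrum$intensity * (target_tic / tic)
  out
}

#' Pointwise mean spectrum of a cohort
#'
#' Arithmetic mean over all spectra (labels and replicate structure are
#' ignored); all spectra must share one grid.
#'
#' @param cohort a `maldi_cohort`.
#' @return a `maldi_spectrum` with ids `"mean"`.
#' @export
mean_spectrum <- function(cohort) {
  mat <- cohort_matrix(cohort)
  new_spectrum(cohort$spectra[[1L]]$mz, rowMeans(mat),
               spectrum_id = "mean", sample_id = "mean")
}

#' Quality-control filter for a cohort
#'
#' Excludes spectra whose raw total ion count is below `min_tic` or whose
#' Pearson correlation with the cohort mean spectrum is below
#' `min_corr_to_mean`.
#'
#' @param cohort a `maldi_cohort` on a common grid.
#' @param min_tic minimum raw total ion count (default 1, i.e. essentially
#'   only empty acquisitions fail on this rule at raw intensity scales).
#' @param min_corr_to_mean minimum Pearson correlation to the cohort mean
#'   (default 0.5).
#' @return list with `cohort` (retained spectra) and `report`, a data frame
#'   with columns `spectrum_id`, `excluded`, `reason` (`"tic"`, `"corr"` or
#'   `""`).
#' @export
qc_filter <- function(cohort, min_tic = 1, min_corr_to_mean = 0.5) {
  mat <- cohort_matrix(cohort)
  tic <- colSums(mat)
  m <- rowMeans(mat)
  corr <- apply(mat, 2L, function(y) {
    if (stats::sd(y) == 0 || stats::sd(m) == 0) return(NA_real_)
    stats::cor(y, m)
  })
  reason <- ifelse(tic < min_tic, "tic",
                   ifelse(is.na(corr) | corr < min_corr_to_mean, "corr", ""))
  excluded <- reason != ""
  report <- data.frame(
    spectrum_id = cohort_spectrum_ids(cohort),
    excluded = excluded, reason = reason,
    stringsAsFactors = FALSE
  )
  if (all(excluded)) stop("all spectra excluded by quality control")
  kept <- new_cohort(cohort$spectra[!excluded], cohort$labels)
  list(cohort = kept, report = report)
}

#' Run the full preprocessing chain on a cohort
#'
#' Resamples every spectrum onto a common grid, applies QC on the raw
#' resampled spectra, estimates and subtracts the baseline per spectrum,
#' and normalizes each spectrum to the target total ion count. Replicates
#' are preprocessed independently; per-sample averaging happens at feature
#' quantification.
#'
#' @param cohort a `maldi_cohort`.
#' @param grid m/z grid; default is a 1 Da grid over the intersection of
#'   all spectrum spans.
#' @param baseline_window_Da baseline window (default 200 Da).
#' @param target_tic total ion count after normalization (default 1).
#' @param min_tic,min_corr_to_mean QC thresholds, see [qc_filter()].
#' @return list with `cohort` (preprocessed spectra), `qc_report`, `grid`,
#'   and `mean` (the mean preprocessed spectrum, input to peak detection).
#' @export
preprocess_cohort <- function(cohort, grid = NULL,
                              baseline_window_Da = 200, target_tic = 1,
                              min_tic = 1, min_corr_to_mean = 0.5) {
  if (!length(cohort$spectra)) stop("empty cohort")
  if (is.null(grid)) {
    lo <- max(vapply(cohort$spectra, function(s) min(s$mz), numeric(1)))
    hi <- min(vapply(cohort$spectra, function(s) max(s$mz), numeric(1)))
    if (lo >= hi) stop("spectra have no common m/z span")
    grid <- seq(ceiling(lo), floor(hi), by = 1)
  }
  res <- new_cohort(lapply(cohort$spectra, resample_spectrum, grid = grid),
                    cohort$labels)
  qc <- qc_filter(res, min_tic = min_tic,
                  min_corr_to_mean = min_corr_to_mean)
  processed <- lapply(qc$cohort$spectra, function(s) {
    b <- estimate_baseline(s, baseline_window_Da)
    normalize_tic(subtract_baseline(s, b), target_tic)
  })
  out <- new_cohort(processed, cohort$labels)
  list(cohort = out, qc_report = qc$report, grid = grid,
       mean = mean_spectrum(out))
}
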