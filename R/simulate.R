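#' Configuration for the synthetic MALDI-TOF cohort generator
#'
#' Describes a linear-mode low-molecular-weight profiling experiment: a case
#' and a control group, a common m/z grid, a set of Gaussian peaks with
#' m/z-proportional width, a smooth exponentially decaying chemical
#' baseline, additive detector noise, a per-sample multiplicative intensity
#' scale (what total-ion-count normalization removes), small per-spectrum
#' m/z jitter, and optional technical replicates.
#'
#' A subset of `n_marker_peaks` peaks carries a class-dependent
#' multiplicative effect: the case-group mean amplitude of marker *i* equals
#' `marker_fold_changes[i]` times its control-group mean amplitude. All
#' remaining `n_background_peaks` peaks are class-independent.
#'
#' @param n_cases,n_controls number of case / control samples (default
#'   35 / 23, a typical discovery-cohort size for this assay).
#' @param mass_range numeric length-2, m/z span in Da.
#' @param grid_step grid spacing in Da.
#' @param n_background_peaks,n_marker_peaks peak counts (defaults 148 + 5 =
#'   153 detectable peaks).
#' @param marker_fold_changes case/control amplitude ratios, recycled to
#'   `n_marker_peaks`; all must be positive.
#' @param peak_height_range length-2 range of base peak amplitudes
#'   (arbitrary intensity units); amplitudes are drawn log-uniformly.
#' @param resolution_factor peak sd = `resolution_factor * m/z`
#'   (linear-TOF behavior).
#' @param baseline_amplitude,baseline_decay_Da baseline
#'   `b(m) = amplitude * exp(-(m - mass_range[1]) / decay)`.
#' @param noise_sd sd of additive Gaussian noise per grid point.
#' @param tic_scale_sd sd (log scale) of the per-sample log-normal
#'   multiplicative intensity scale; technical replicates of one sample
#'   share its scale factor.
#' @param sample_peak_cv sd (log scale) of the per-sample, per-peak
#'   log-normal biological amplitude factor, also shared by a sample's
#'   replicates (default 0.35, a mid-range inter-subject CV for biofluid
#'   peptide abundances). This is what makes replicates cluster by
#'   biological origin and keeps case/control separation imperfect, as in
#'   real profiling cohorts; set to 0 for deterministic amplitudes.
#' @param mz_jitter_sd sd in Da of the per-spectrum, per-peak center jitter.
#' @param n_replicates technical replicates per sample.
#' @param seed integer seed; the full cohort is reproducible from it.
#' @return an object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_cases = 4, n_controls = 4, n_background_peaks = 20,
#'                   n_marker_peaks = 2, marker_fold_changes = c(0.8, 1.5))
sim_config <- function(n_cases = 35L, n_controls = 23L,
                       mass_range = c(1000, 10000), grid_step = 1,
                       n_background_peaks = 148L, n_marker_peaks = 5L,
                       marker_fold_changes = c(0.79, 0.90, 0.94, 0.96, 1.5),
                       peak_height_range = c(10, 100),
                       resolution_factor = 0.002,
                       baseline_amplitude = 20, baseline_decay_Da = 3000,
                       noise_sd = 1, tic_scale_sd = 0.2,
                       sample_peak_cv = 0.35, mz_jitter_sd = 0.5,
                       n_replicates = 1L, seed = 1L) {
  if (n_cases < 1 || n_controls < 1) stop("n_cases and n_controls must be >= 1")
  if (grid_step <= 0) stop("grid_step must be positive")
  if (length(mass_range) != 2L || mass_range[1] >= mass_range[2]) {
    stop("mass_range must be [low, high] with low < high")
  }
  if (n_background_peaks < 0 || n_marker_peaks < 0) stop("peak counts must be >= 0")
  if (n_background_peaks + n_marker_peaks < 1) stop("need at least one peak")
  marker_fold_changes <-
    if (n_marker_peaks > 0) rep_len(as.numeric(marker_fold_changes), n_marker_peaks)
    else numeric(0)
  if (any(marker_fold_changes <= 0)) stop("fold changes must be positive")
  if (length(peak_height_range) != 2L || any(peak_height_range <= 0) ||
      peak_height_range[1] > peak_height_range[2]) {
    stop("peak_height_range must be positive [low, high]")
  }
  if (resolution_factor <= 0) stop("resolution_factor must be positive")
  if (noise_sd < 0 || tic_scale_sd < 0 || sample_peak_cv < 0 ||
      mz_jitter_sd < 0) {
    stop("noise parameters must be non-negative")
  }
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  structure(
    list(
      n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
      mass_range = as.numeric(mass_range), grid_step = as.numeric(grid_step),
      n_background_peaks = as.integer(n_background_peaks),
      n_marker_peaks = as.integer(n_marker_peaks),
      marker_fold_changes = marker_fold_changes,
      peak_height_range = as.numeric(peak_height_range),
      resolution_factor = as.numeric(resolution_factor),
      baseline_amplitude = as.numeric(baseline_amplitude),
      baseline_decay_Da = as.numeric(baseline_decay_Da),
      noise_sd = as.numeric(noise_sd),
      tic_scale_sd = as.numeric(tic_scale_sd),
      sample_peak_cv = as.numeric(sample_peak_cv),
      mz_jitter_sd = as.numeric(mz_jitter_sd),
      n_replicates = as.integer(n_replicates),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Draw peak centers log-uniformly over the usable mass range, rejecting
# candidates closer than 4 combined peak sd to an accepted center, so
# neighboring peaks never fuse. Log-uniform placement concentrates peaks at
# low m/z, as matrix-assisted profiling spectra do.
draw_peak_centers <- function(n, config) {
  r <- config$resolution_factor
  lo <- config$mass_range[1] / (1 - 5 * r)
  hi <- config$mass_range[2] / (1 + 5 * r)
  if (lo >= hi) stop("mass_range too narrow for the requested resolution")
  centers <- numeric(0)
  tries <- 0L
  while (length(centers) < n) {
    tries <- tries + 1L
    if (tries > 1000L * n) {
      stop("could not place ", n, " peaks with the required separation")
    }
    cand <- exp(stats::runif(1, log(lo), log(hi)))
    if (!length(centers) ||
        all(abs(cand - centers) >= 4 * r * pmax(cand, centers))) {
      centers <- c(centers, cand)
    }
  }
  centers
}

baseline_curve <- function(grid, config) {
  config$baseline_amplitude *
    exp(-(grid - config$mass_range[1]) / config$baseline_decay_Da)
}

#' Generate a labeled synthetic profile-spectrum cohort with known truth
#'
#' Each spectrum is the sum of Gaussian peaks
#' `A_is * exp(-(m - c_i - jitter_i)^2 / (2 sigma_i^2))` with
#' `sigma_i = resolution_factor * c_i`, plus the exponential baseline and
#' additive Gaussian noise, all multiplied by the sample's log-normal scale
#' factor. The amplitude of peak `i` in sample `s` is
#' `A_is = A_i * FC_i^[s is a case] * exp(eps_is)` with
#' `eps_is ~ N(0, sample_peak_cv^2)` shared by the sample's replicates, so
#' the case-group mean amplitude of a marker equals `fold_change` times the
#' control-group mean (exactly when `sample_peak_cv = 0`, in expectation
#' otherwise).
#'
#' The draw order under `config$seed` is fixed (centers, marker assignment,
#' amplitudes, then per sample its scale and biological factors, then per
#' spectrum jitter and noise in acquisition order), so the same
#' configuration always yields bit-identical spectra.
#'
#' @param config a [sim_config()].
#' @return list with elements `cohort` (a `maldi_cohort`) and `truth`
#'   (class `sim_truth`: `marker_centers`, `marker_fold_changes`,
#'   `background_centers`, `sample_scale`, `marker_amplitudes`).
#' @export
#' @examples
#' sim <- generate_cohort(sim_config(n_cases = 3, n_controls = 3,
#'                                   n_background_peaks = 10,
#'                                   n_marker_peaks = 1,
#'                                   marker_fold_changes = 2))
#' sim$cohort
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  set.seed(config$seed)
  grid <- seq(config$mass_range[1], config$mass_range[2],
              by = config$grid_step)
  n_peaks <- config$n_background_peaks + config$n_marker_peaks
  centers <- draw_peak_centers(n_peaks, config)
  ord <- order(centers)
  centers <- centers[ord]
  marker_idx <- if (config$n_marker_peaks > 0) {
    sort(sample.int(n_peaks, config$n_marker_peaks))
  } else integer(0)
  amp <- exp(stats::runif(n_peaks, log(config$peak_height_range[1]),
                          log(config$peak_height_range[2])))
  fc <- rep(1, n_peaks)
  fc[marker_idx] <- config$marker_fold_changes
  sds <- config$resolution_factor * centers

  n_samples <- config$n_cases + config$n_controls
  sample_ids <- c(sprintf("case_%02d", seq_len(config$n_cases)),
                  sprintf("control_%02d", seq_len(config$n_controls)))
  labels <- stats::setNames(
    rep(c("case", "control"), c(config$n_cases, config$n_controls)),
    sample_ids
  )
  sample_scale <- numeric(n_samples)
  sample_bio <- matrix(0, nrow = n_peaks, ncol = n_samples)
  for (s in seq_len(n_samples)) {
    sample_scale[s] <- exp(stats::rnorm(1, 0, config$tic_scale_sd))
    sample_bio[, s] <- stats::rnorm(n_peaks, 0, config$sample_peak_cv)
  }
  names(sample_scale) <- sample_ids
  base <- baseline_curve(grid, config)

  spectra <- vector("list", n_samples * config$n_replicates)
  k <- 0L
  for (s in seq_len(n_samples)) {
    a <- amp * exp(sample_bio[, s]) *
      if (labels[[s]] == "case") fc else 1
    for (r in seq_len(config$n_replicates)) {
      jit <- stats::rnorm(n_peaks, 0, config$mz_jitter_sd)
      y <- base + numeric(length(grid))
      for (p in seq_len(n_peaks)) {
        c_p <- centers[p] + jit[p]
        idx <- which(grid >= c_p - 6 * sds[p] & grid <= c_p + 6 * sds[p])
        if (length(idx)) {
          y[idx] <- y[idx] + a[p] * exp(-(grid[idx] - c_p)^2 / (2 * sds[p]^2))
        }
      }
      y <- (y + stats::rnorm(length(grid), 0, config$noise_sd)) *
        sample_scale[[s]]
      k <- k + 1L
      spectra[[k]] <- new_spectrum(
        grid, y,
        spectrum_id = sprintf("%s_r%d", sample_ids[s], r),
        sample_id = sample_ids[s], replicate = r, label = labels[[s]]
      )
    }
  }

  truth <- structure(
    list(
      marker_centers = centers[marker_idx],
      marker_fold_changes = fc[marker_idx],
      marker_amplitudes = amp[marker_idx],
      background_centers = centers[setdiff(seq_len(n_peaks), marker_idx)],
      sample_scale = sample_scale
    ),
    class = "sim_truth"
  )
  list(cohort = new_cohort(spectra, labels), truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "<sim_truth> %d marker peak(s), %d background peak(s), %d sample scale factor(s)\n",
    length(x$marker_centers), length(x$background_centers),
    length(x$sample_scale)
  ))
  if (length(x$marker_centers)) {
    cat("  markers:",
        paste(sprintf("%.2f (FC %.2f)", x$marker_centers,
                      x$marker_fold_changes), collapse = ", "), "\n")
  }
  invisible(x)
}
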