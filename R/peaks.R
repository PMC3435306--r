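# Peak detection on the cohort mean spectrum and quantification of every
# sample at the detected peaks.

#' Construct a peak set
#'
#' @param centers peak centers in Da, strictly ascending.
#' @param half_widths quantification window half-widths in Da, one per peak.
#' @param snr signal-to-noise ratio at detection, one per peak.
#' @return an object of class `peak_set`.
#' @export
new_peakset <- function(centers, half_widths, snr = rep(NA_real_, length(centers))) {
  centers <- as.numeric(centers)
  half_widths <- as.numeric(half_widths)
  if (length(half_widths) != length(centers) || length(snr) != length(centers)) {
    stop("centers, half_widths and snr must have equal length")
  }
  if (length(centers) > 1L && any(diff(centers) <= 0)) {
    stop("centers must be strictly ascending")
  }
  if (any(half_widths < 0)) stop("half_widths must be non-negative")
  if (length(centers) > 1L &&
      any(centers[-length(centers)] + half_widths[-length(centers)] >
          centers[-1L] - half_widths[-1L] + 1e-9)) {
    stop("quantification windows overlap")
  }
  structure(
    list(centers = centers, half_widths = half_widths,
         snr = as.numeric(snr), peak_ids = make_peak_ids(centers)),
    class = "peak_set"
  )
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peak(s)", length(x$centers)))
  if (length(x$centers)) {
    cat(sprintf(", m/z %.2f-%.2f", min(x$centers), max(x$centers)))
  }
  cat("\n")
  invisible(x)
}

# Peak ids are masses rounded to 2 decimals; collisions get letter
# suffixes "_b", "_c", ... in ascending-mass order.
make_peak_ids <- function(centers) {
  ids <- sprintf("%.2f", centers)
  dup <- ids[duplicated(ids)]
  for (d in unique(dup)) {
    at <- which(ids == d)
    ids[at[-1L]] <- paste0(d, "_", letters[1L + seq_along(at[-1L])])
  }
  ids
}

#' Detect peaks on a preprocessed mean spectrum
#'
#' Local maxima of the lightly smoothed mean spectrum are kept when their
#' height divided by the local noise level reaches `snr_min`. Height is
#' measured above a running-median trend over the noise window, which
#' absorbs the small positive offset that zero-clamped baseline correction
#' leaves in signal-free regions. Local noise is the median absolute
#' deviation of the detrended signal (spectrum minus its smooth) in a
#' sliding `noise_window_Da` window, scaled by 1.4826 to the standard
#' deviation of a normal. Retained maxima are greedily thinned so they are
#' at least `min_separation_Da` apart, keeping the higher peak (ties keep
#' the lower m/z). Each peak's quantification half-width is half the
#' distance to its nearest retained neighbor, capped at
#' `max_half_width_rel` times the center mass.
#'
#' Detection is scale-free: multiplying the spectrum by a positive constant
#' leaves the detected centers unchanged.
#'
#' @param mean_spec the mean preprocessed `maldi_spectrum`.
#' @param snr_min minimum signal-to-noise ratio (default 2).
#' @param min_separation_Da minimum distance between retained peaks
#'   (default 5 Da).
#' @param noise_window_Da width of the sliding noise-estimation window
#'   (default 250 Da).
#' @param smooth_Da width of the pre-detection smoothing window
#'   (default 5 Da).
#' @param max_half_width_rel cap on the window half-width as a fraction of
#'   the center mass (default 0.003).
#' @return a `peak_set`; empty (zero peaks) for an all-zero spectrum.
#' @export
detect_peaks <- function(mean_spec, snr_min = 2, min_separation_Da = 5,
                         noise_window_Da = 250, smooth_Da = 5,
                         max_half_width_rel = 0.003) {
  mz <- mean_spec$mz
  y <- mean_spec$intensity
  step <- stats::median(diff(mz))
  empty <- new_peakset(numeric(0), numeric(0), numeric(0))
  if (all(y == 0)) return(empty)

  ys <- moving_average(y, window_points(smooth_Da, step))
  resid <- y - ys
  k_noise <- min(window_points(noise_window_Da, step),
                 2L * (length(y) %/% 2L) - 1L)
  noise <- 1.4826 * stats::runmed(abs(resid), k_noise, endrule = "constant")
  floor_ <- 1e-12 * max(abs(ys))
  noise <- pmax(noise, floor_)
  trend <- stats::runmed(ys, k_noise, endrule = "median")
  height <- ys - trend

  n <- length(ys)
  i <- 2:(n - 1L)
  is_max <- ys[i] > ys[i - 1L] & ys[i] >= ys[i + 1L]
  cand <- i[is_max]
  cand <- cand[height[cand] / noise[cand] >= snr_min]
  if (!length(cand)) return(empty)

  # greedy thinning: highest first, ties to lower m/z
  ord <- cand[order(-height[cand], mz[cand])]
  kept <- integer(0)
  for (j in ord) {
    if (!length(kept) || all(abs(mz[j] - mz[kept]) >= min_separation_Da)) {
      kept <- c(kept, j)
    }
  }
  kept <- sort(kept)
  centers <- mz[kept]

  hw <- if (length(centers) == 1L) {
    max_half_width_rel * centers
  } else {
    gaps <- diff(centers)
    nearest <- pmin(c(gaps[1L], gaps), c(gaps, gaps[length(gaps)]))
    pmin(nearest / 2, max_half_width_rel * centers)
  }
  new_peakset(centers, hw, height[kept] / noise[kept])
}

#' Construct a samples x peaks feature matrix
#'
#' @param values numeric matrix, samples in rows, peaks in columns.
#' @param sample_ids row identities.
#' @param labels per-sample class labels (`"case"` / `"control"`).
#' @param peak_ids column identities.
#' @param centers optional peak centers in Da (kept for reporting).
#' @return an object of class `feature_matrix`.
#' @export
new_feature_matrix <- function(values, sample_ids, labels, peak_ids,
                               centers = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != length(sample_ids) || nrow(values) != length(labels)) {
    stop("values rows must match sample_ids and labels")
  }
  if (ncol(values) != length(peak_ids)) {
    stop("values columns must match peak_ids")
  }
  if (anyNA(values)) stop("feature matrix must not contain missing values")
  labels <- as.character(labels)
  if (!all(labels %in% c("case", "control"))) {
    stop("labels must be 'case' or 'control'")
  }
  dimnames(values) <- list(sample_ids, peak_ids)
  structure(
    list(values = values, sample_ids = as.character(sample_ids),
         labels = labels, peak_ids = as.character(peak_ids),
         centers = centers),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d sample(s) (%d case / %d control) x %d peak(s)\n",
    nrow(x$values), sum(x$labels == "case"), sum(x$labels == "control"),
    ncol(x$values)
  ))
  invisible(x)
}

# column subset preserving structure
fm_subset <- function(fm, peak_ids = NULL, sample_idx = NULL) {
  v <- fm$values
  cen <- fm$centers
  if (!is.null(peak_ids)) {
    j <- match(peak_ids, fm$peak_ids)
    if (anyNA(j)) stop("unknown peak id(s)")
    v <- v[, j, drop = FALSE]
    if (!is.null(cen)) cen <- cen[j]
  }
  ids <- fm$sample_ids
  lab <- fm$labels
  if (!is.null(sample_idx)) {
    v <- v[sample_idx, , drop = FALSE]
    ids <- ids[sample_idx]
    lab <- lab[sample_idx]
  }
  new_feature_matrix(v, ids, lab, colnames(v), centers = cen)
}

#' Quantify every sample at a set of peaks
#'
#' The feature value of a sample at a peak is the maximum preprocessed
#' (baseline-corrected, normalized) intensity inside the peak's
#' quantification window, averaged over the sample's technical replicates.
#'
#' @param cohort a preprocessed `maldi_cohort` on one common grid.
#' @param peakset a `peak_set` whose windows lie inside that grid.
#' @return a `feature_matrix` with one row per sample (not per spectrum).
#' @export
quantify <- function(cohort, peakset) {
  mat <- cohort_matrix(cohort)
  mz <- cohort$spectra[[1L]]$mz
  p <- length(peakset$centers)
  win <- lapply(seq_len(p), function(j) {
    idx <- which(mz >= peakset$centers[j] - peakset$half_widths[j] &
                 mz <= peakset$centers[j] + peakset$half_widths[j])
    if (!length(idx)) {
      stop(sprintf("window of peak %s (m/z %.2f) outside the grid",
                   peakset$peak_ids[j], peakset$centers[j]))
    }
    idx
  })
  per_spectrum <- vapply(seq_len(ncol(mat)), function(s) {
    vapply(win, function(idx) max(mat[idx, s]), numeric(1))
  }, numeric(p))
  per_spectrum <- matrix(per_spectrum, nrow = p) # p x spectra

  sids <- cohort_sample_ids(cohort)
  samples <- unique(sids)
  vals <- t(vapply(samples, function(s) {
    rowMeans(per_spectrum[, sids == s, drop = FALSE])
  }, numeric(p)))
  vals <- matrix(vals, nrow = length(samples))
  new_feature_matrix(vals, samples, cohort$labels[samples],
                     peakset$peak_ids, centers = peakset$centers)
}
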