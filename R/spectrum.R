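#' Construct a profile mass spectrum
#'
#' A spectrum is an m/z grid with one intensity per grid point plus the
#' identity of the acquisition it came from: a spectrum id (unique per
#' acquisition), a sample id (shared by technical replicates of one
#' specimen), a replicate number, and an optional class label.
#'
#' @param mz numeric vector of m/z values in Da, strictly ascending.
#' @param intensity numeric vector of intensities (arbitrary units), same
#'   length as `mz`.
#' @param spectrum_id,sample_id character scalars identifying the
#'   acquisition and the specimen.
#' @param replicate integer replicate number within the sample.
#' @param label optional class label, `"case"` or `"control"`.
#' @return an object of class `maldi_spectrum`.
#' @export
#' @examples
#' s <- new_spectrum(seq(1000, 1010), rep(1, 11), "s1", "p1")
new_spectrum <- function(mz, intensity, spectrum_id, sample_id,
                         replicate = 1L, label = NULL) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) < 2L) stop("spectrum must have at least 2 points")
  if (length(mz) != length(intensity)) {
    stop("mz and intensity lengths differ")
  }
  if (any(diff(mz) <= 0)) stop("mz must be strictly ascending")
  if (!all(is.finite(intensity))) stop("intensities must be finite")
  if (!is.null(label)) label <- match.arg(label, c("case", "control"))
  structure(
    list(
      mz = mz, intensity = intensity,
      spectrum_id = as.character(spectrum_id),
      sample_id = as.character(sample_id),
      replicate = as.integer(replicate),
      label = label
    ),
    class = "maldi_spectrum"
  )
}

#' @export
print.maldi_spectrum <- function(x, ...) {
  cat(sprintf(
    "<maldi_spectrum> %s (sample %s, replicate %d)\n  %d points, m/z %.2f-%.2f, TIC %.4g\n",
    x$spectrum_id, x$sample_id, x$replicate, length(x$mz),
    min(x$mz), max(x$mz), sum(x$intensity)
  ))
  invisible(x)
}

#' Construct a labeled cohort of spectra
#'
#' @param spectra list of [new_spectrum()] objects.
#' @param labels named character vector mapping every `sample_id` occurring
#'   in `spectra` to `"case"` or `"control"`.
#' @return an object of class `maldi_cohort` with elements `spectra` and
#'   `labels`.
#' @export
new_cohort <- function(spectra, labels) {
  stopifnot(is.list(spectra))
  labels <- vapply(labels, as.character, character(1))
  if (length(labels) && !all(labels %in% c("case", "control"))) {
    stop("labels must be 'case' or 'control'")
  }
  sids <- vapply(spectra, function(s) s$sample_id, character(1))
  missing <- setdiff(unique(sids), names(labels))
  if (length(missing)) {
    stop("no label for sample(s): ", paste(missing, collapse = ", "))
  }
  structure(list(spectra = spectra, labels = labels), class = "maldi_cohort")
}

#' @export
print.maldi_cohort <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("case", "control")))
  cat(sprintf(
    "<maldi_cohort> %d spectra from %d samples (%d case / %d control)\n",
    length(x$spectra), length(x$labels), tab[["case"]], tab[["control"]]
  ))
  invisible(x)
}

#' Number of spectra in a cohort
#' @param x a `maldi_cohort`.
#' @export
#' @keywords internal
length.maldi_cohort <- function(x) length(x$spectra)

# intensities of all spectra as a grid-points x spectra matrix;
# errors if the spectra are not on one common grid.
cohort_matrix <- function(cohort) {
  if (!length(cohort$spectra)) stop("empty cohort")
  mz0 <- cohort$spectra[[1L]]$mz
  same <- vapply(cohort$spectra, function(s) {
    length(s$mz) == length(mz0) && isTRUE(all.equal(s$mz, mz0, tolerance = 0))
  }, logical(1))
  if (!all(same)) stop("spectra are not on a common m/z grid")
  vapply(cohort$spectra, function(s) s$intensity, numeric(length(mz0)))
}

cohort_spectrum_ids <- function(cohort) {
  vapply(cohort$spectra, function(s) s$spectrum_id, character(1))
}

cohort_sample_ids <- function(cohort) {
  vapply(cohort$spectra, function(s) s$sample_id, character(1))
}
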