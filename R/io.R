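# Plain-text interchange formats.
#
# Spectrum files: two whitespace-separated columns (m/z, intensity),
# ascending m/z, with "#"-prefixed header lines carrying the spectrum
# identity. Sample sheet: CSV with columns
# spectrum_id,sample_id,replicate,label (label in {case, control}).
# Ground truth: JSON with keys marker_centers, marker_fold_changes,
# marker_amplitudes, background_centers, sample_scale.

#' Write one spectrum as two-column text
#'
#' @param spectrum a `maldi_spectrum`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_txt <- function(spectrum, path) {
  header <- c(
    sprintf("# spectrum_id: %s", spectrum$spectrum_id),
    sprintf("# sample_id: %s", spectrum$sample_id),
    sprintf("# replicate: %d", spectrum$replicate),
    if (!is.null(spectrum$label)) sprintf("# label: %s", spectrum$label)
  )
  body <- sprintf("%.10g %.10g", spectrum$mz, spectrum$intensity)
  ok <- tryCatch({
    writeLines(c(header, body), path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write spectrum to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read one two-column text spectrum
#'
#' @param path file written by [write_spectrum_txt()] (or any two-column
#'   m/z intensity text file; identity fields then fall back to the file
#'   name).
#' @param spectrum_id,sample_id,replicate,label overrides for the identity
#'   fields; defaults come from the `#` header lines.
#' @return a `maldi_spectrum`.
#' @export
read_spectrum_txt <- function(path, spectrum_id = NULL, sample_id = NULL,
                              replicate = NULL, label = NULL) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(name) {
    m <- grep(sprintf("^# %s:", name), hdr, value = TRUE)
    if (length(m)) trimws(sub(sprintf("^# %s:", name), "", m[1])) else NULL
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(body), "\\s+")
  mz <- as.numeric(vapply(parts, `[[`, character(1), 1L))
  it <- as.numeric(vapply(parts, `[[`, character(1), 2L))
  fallback_id <- sub("\\.[^.]*$", "", basename(path))
  new_spectrum(
    mz, it,
    spectrum_id = spectrum_id %||% get_field("spectrum_id") %||% fallback_id,
    sample_id = sample_id %||% get_field("sample_id") %||% fallback_id,
    replicate = as.integer(replicate %||% get_field("replicate") %||% 1L),
    label = label %||% get_field("label")
  )
}

#' Write a cohort (spectrum files, sample sheet, optional truth JSON)
#'
#' @param cohort a `maldi_cohort`; may be empty, in which case only a
#'   header-only sample sheet is written.
#' @param directory output directory (created if needed).
#' @param truth optional `sim_truth` written as `truth.json`.
#' @return character vector of the written file paths, invisibly.
#' @export
write_cohort <- function(cohort, directory, truth = NULL) {
  ok <- dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  sheet <- data.frame(
    spectrum_id = cohort_spectrum_ids(cohort),
    sample_id = cohort_sample_ids(cohort),
    replicate = vapply(cohort$spectra, function(s) s$replicate, integer(1)),
    label = vapply(cohort$spectra, function(s) s$label %||% NA_character_,
                   character(1)),
    stringsAsFactors = FALSE
  )
  sheet_path <- file.path(directory, "sample_sheet.csv")
  utils::write.csv(sheet, sheet_path, row.names = FALSE, quote = FALSE)
  paths <- vapply(cohort$spectra, function(s) {
    p <- file.path(directory, paste0(s$spectrum_id, ".txt"))
    write_spectrum_txt(s, p)
    p
  }, character(1))
  written <- c(sheet_path, paths)
  if (!is.null(truth)) {
    truth_path <- file.path(directory, "truth.json")
    jsonlite::write_json(unclass(truth), truth_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, truth_path)
  }
  invisible(written)
}

#' Read a cohort from a directory written by [write_cohort()]
#'
#' @param directory directory containing `sample_sheet.csv` and one
#'   `<spectrum_id>.txt` per spectrum.
#' @return a `maldi_cohort`.
#' @export
read_cohort <- function(directory) {
  sheet_path <- file.path(directory, "sample_sheet.csv")
  if (!file.exists(sheet_path)) stop("sample sheet not found: ", sheet_path)
  sheet <- utils::read.csv(sheet_path, stringsAsFactors = FALSE)
  spectra <- lapply(seq_len(nrow(sheet)), function(i) {
    p <- file.path(directory, paste0(sheet$spectrum_id[i], ".txt"))
    read_spectrum_txt(
      p,
      spectrum_id = sheet$spectrum_id[i], sample_id = sheet$sample_id[i],
      replicate = sheet$replicate[i],
      label = if (is.na(sheet$label[i])) NULL else sheet$label[i]
    )
  })
  labels <- stats::setNames(sheet$label, sheet$sample_id)
  labels <- labels[!duplicated(names(labels)) & !is.na(labels)]
  new_cohort(spectra, labels)
}

#' Read a ground-truth JSON file
#' @param path path to a `truth.json` written by [write_cohort()].
#' @return a `sim_truth`.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("marker_centers", "marker_fold_changes", "marker_amplitudes",
              "background_centers")) {
    x[[f]] <- as.numeric(unlist(x[[f]]))
  }
  x$sample_scale <- unlist(x$sample_scale)
  structure(x, class = "sim_truth")
}

#' Write / read a peak set as CSV
#'
#' Columns: `center`, `half_width`, `snr`.
#' @param peakset a `peak_set`.
#' @param path CSV path.
#' @return `write_peakset_csv()` returns `path` invisibly;
#'   `read_peakset_csv()` returns a `peak_set`.
#' @export
write_peakset_csv <- function(peakset, path) {
  df <- data.frame(center = peakset$centers,
                   half_width = peakset$half_widths,
                   snr = peakset$snr)
  utils::write.csv(format(df, digits = 12, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_peakset_csv
#' @export
read_peakset_csv <- function(path) {
  df <- utils::read.csv(path)
  new_peakset(df$center, df$half_width, df$snr)
}

#' Write / read a feature matrix as CSV
#'
#' One row per sample; columns `sample_id`, `label`, then one column per
#' peak id.
#' @param fm a `feature_matrix`.
#' @param path CSV path.
#' @return `write_features_csv()` returns `path` invisibly;
#'   `read_features_csv()` returns a `feature_matrix`.
#' @export
write_features_csv <- function(fm, path) {
  df <- data.frame(sample_id = fm$sample_ids, label = fm$labels,
                   stringsAsFactors = FALSE, check.names = FALSE)
  vals <- as.data.frame(fm$values, check.names = FALSE)
  names(vals) <- fm$peak_ids
  df <- cbind(df, format(vals, digits = 12, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, setdiff(names(df), c("sample_id", "label")),
                       drop = FALSE])
  storage.mode(vals) <- "double"
  new_feature_matrix(vals, sample_ids = df$sample_id, labels = df$label,
                     peak_ids = colnames(vals))
}
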