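# Univariate screening: two-sided Wilcoxon rank-sum tests, fold changes as
# ratios of class means, and significance tiers.

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Midranks are used for ties. In `"auto"` mode the exact null distribution
#' is enumerated when the smaller group has at most 8 observations and the
#' pooled values are tie-free; otherwise the normal approximation with tie
#' correction and continuity correction is used. Typical profiling group
#' sizes (tens per class) fall safely in the approximation regime.
#'
#' @param x,y numeric samples from the two groups, each non-empty.
#' @param mode `"auto"` (default), `"exact"`, or `"asymptotic"`.
#' @return two-sided p-value in (0, 1].
#' @export
#' @examples
#' wilcoxon_two_sided(1:3, 4:6)  # 0.1 = 2 / choose(6, 3)
wilcoxon_two_sided <- function(x, y, mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- switch(mode,
    auto = min(length(x), length(y)) <= 8L && !ties,
    exact = TRUE,
    asymptotic = FALSE
  )
  if (exact && ties) {
    stop("exact mode is undefined with tied values; use mode = 'asymptotic'")
  }
  p <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "two.sided", exact = exact, correct = TRUE
  )$p.value)
  min(p, 1)
}

#' Fold change as the ratio of class means
#'
#' `mean(case) / mean(control)`; values below 1 mean down-regulated in
#' cases, above 1 up-regulated.
#'
#' @param case_values,control_values numeric vectors; the control mean must
#'   be positive.
#' @return positive ratio.
#' @export
#' @examples
#' fold_change(c(2, 4), c(1, 3))  # 1.5
fold_change <- function(case_values, control_values) {
  m0 <- mean(as.numeric(control_values))
  if (!is.finite(m0) || m0 <= 0) {
    stop("fold change undefined: control mean must be positive")
  }
  mean(as.numeric(case_values)) / m0
}

tier_of <- function(p) {
  ifelse(p <= 0.05, "significant", ifelse(p <= 0.1, "trend", "ns"))
}

#' Univariate screening table for a feature matrix or concentration table
#'
#' For every feature: two-sided Wilcoxon rank-sum p-value, fold change
#' (case mean / control mean), regulation direction, and significance tier
#' (`significant` for p <= 0.05, `trend` for 0.05 < p <= 0.1, `ns`
#' otherwise, the conventional raw-p tiers for this assay). A
#' Benjamini-Hochberg adjusted p-value column `p_adj_bh` is appended as
#' supplementary output; the tiers are based on the raw p-values.
#'
#' @param features a `feature_matrix`, or a data frame / matrix of
#'   per-sample values (rows = samples, columns = analytes) with `labels`
#'   supplied separately — the shape of an external ELISA / MRM
#'   concentration table.
#' @param labels optional `"case"`/`"control"` vector when `features` is
#'   not a `feature_matrix`.
#' @param mode Wilcoxon mode, see [wilcoxon_two_sided()].
#' @return data frame with columns `feature`, `p_value`, `fold_change`,
#'   `direction` (`up`/`down`/`flat`), `tier`, `p_adj_bh`.
#' @export
univariate_table <- function(features, labels = NULL,
                             mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  inp <- as_feature_input(features, labels)
  check_two_classes(inp$y)
  if (min(table(inp$y)) < 2L) stop("at least 2 samples per class required")
  is_case <- inp$y == "case"
  res <- lapply(seq_len(ncol(inp$x)), function(j) {
    v <- inp$x[, j]
    if (length(unique(v)) == 1L) {
      warning("feature ", inp$ids[j], " is constant; p set to 1")
      p <- 1
    } else {
      p <- wilcoxon_two_sided(v[is_case], v[!is_case], mode = mode)
    }
    fc <- if (mean(v[!is_case]) > 0) {
      fold_change(v[is_case], v[!is_case])
    } else {
      warning("feature ", inp$ids[j],
              " has non-positive control mean; fold change set to NA")
      NA_real_
    }
    data.frame(feature = inp$ids[j], p_value = p, fold_change = fc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$direction <- ifelse(is.na(out$fold_change), NA_character_,
                          ifelse(out$fold_change > 1, "up",
                                 ifelse(out$fold_change < 1, "down", "flat")))
  out$tier <- tier_of(out$p_value)
  out$p_adj_bh <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Read an external per-sample concentration table
#'
#' Expects a CSV with rows as samples and columns as analytes, one
#' `sample_id` column, and one label column with values `case`/`control`
#' (the shape of a wide ELISA or targeted-MS concentration export).
#'
#' @param path CSV path.
#' @param label_col name of the label column (default `"label"`).
#' @param sample_col name of the sample-id column (default `"sample_id"`;
#'   absent is tolerated).
#' @return a `feature_matrix` (usable directly in [univariate_table()]).
#' @export
read_concentration_table <- function(path, label_col = "label",
                                     sample_col = "sample_id") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!label_col %in% names(df)) {
    stop("label column '", label_col, "' not found in ", path)
  }
  labels <- as.character(df[[label_col]])
  ids <- if (sample_col %in% names(df)) as.character(df[[sample_col]]) else
    as.character(seq_len(nrow(df)))
  vals <- as.matrix(df[, setdiff(names(df), c(label_col, sample_col)),
                       drop = FALSE])
  storage.mode(vals) <- "double"
  new_feature_matrix(vals, ids, labels, colnames(vals))
}
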