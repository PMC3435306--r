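# Recursive feature elimination by median mean decrease in accuracy, and
# nested cross-validated performance with the elimination run inside each
# training fold.

#' Which features survive one median-MDA elimination round
#'
#' Implements the elimination rule literally: a feature is removed when its
#' mean decrease in accuracy is *strictly below* the median MDA of the
#' current set; features exactly at the median are kept. With pairwise
#' distinct importances this deletes `floor(n/2)` features per round, giving
#' the deterministic schedule 153 -> 77 -> 39 -> 20 -> 10 -> 5 -> 3 -> 2.
#'
#' @param mda numeric vector of per-feature mean decrease in accuracy.
#' @return logical vector, `TRUE` for features that are kept.
#' @export
#' @examples
#' sum(median_mda_keep(c(3, 1, 4, 1.5, 9)))  # 3 of 5 survive
median_mda_keep <- function(mda) {
  mda >= stats::median(mda)
}

#' Panel selection by recursive feature elimination
#'
#' Starting from the full feature set, repeatedly fits a forest, computes
#' MDA importance, and removes every feature strictly below the median MDA,
#' recording each set, until fewer than two features would remain (or a
#' round removes nothing, which can only happen with tied importances).
#' Every recorded set — including the full set — is then scored by
#' [repeated_cv()] with the set held fixed, and the set with the highest
#' pooled cross-validation AUC is selected; AUC ties go to the smaller set.
#'
#' Note the selection here uses class information on the full data; an
#' unbiased generalization estimate for the selected panel size comes from
#' [nested_performance()].
#'
#' @param features a `feature_matrix` with at least 2 features.
#' @param n_trees trees per forest (elimination and scoring).
#' @param mtry features tried per split; default `floor(sqrt(p))` per set.
#' @param cv_folds,cv_repetitions geometry of the scoring cross-validation.
#' @param seed master seed.
#' @return an object of class `rfe_trace`: `sets` (list of feature-id
#'   vectors), `sizes`, `cv_auc`, `cv_results` (list of `cv_result`),
#'   `selected_index`, `selected_features`, `selected_cv`.
#' @export
rfe <- function(features, n_trees = 500, mtry = NULL, cv_folds = 10,
                cv_repetitions = 10, seed = 1L) {
  stopifnot(inherits(features, "feature_matrix"))
  if (ncol(features$values) < 2L) stop("rfe needs at least 2 features")
  seeds <- derive_seeds(seed, 2L)
  elim_seeds <- derive_seeds(seeds[1L], 64L)
  sets <- list(features$peak_ids)
  current <- features$peak_ids
  round <- 0L
  repeat {
    round <- round + 1L
    model <- fit_forest(fm_subset(features, peak_ids = current),
                        n_trees = n_trees, mtry = mtry,
                        seed = elim_seeds[round], importance = TRUE)
    keep <- median_mda_keep(model$mda)
    if (sum(keep) < 2L || all(keep)) break
    current <- current[keep]
    sets <- c(sets, list(current))
  }
  score_seeds <- derive_seeds(seeds[2L], length(sets))
  cv_results <- lapply(seq_along(sets), function(i) {
    repeated_cv(fm_subset(features, peak_ids = sets[[i]]),
                n_folds = cv_folds, n_repetitions = cv_repetitions,
                n_trees = n_trees, mtry = mtry, seed = score_seeds[i])
  })
  auc <- vapply(cv_results, `[[`, numeric(1), "auc")
  # sets are recorded in strictly decreasing size, so the last index
  # attaining the maximum is the smallest set among AUC ties
  best <- max(which(auc == max(auc)))
  structure(
    list(
      sets = sets,
      sizes = lengths(sets),
      cv_auc = auc,
      cv_results = cv_results,
      selected_index = best,
      selected_features = sets[[best]],
      selected_cv = cv_results[[best]],
      seed = seed
    ),
    class = "rfe_trace"
  )
}

#' @export
print.rfe_trace <- function(x, ...) {
  cat(sprintf(
    "<rfe_trace> %d set(s): sizes %s\n  selected %d feature(s), CV AUC %.3f\n",
    length(x$sets), paste(x$sizes, collapse = " -> "),
    length(x$selected_features), x$cv_auc[x$selected_index]
  ))
  invisible(x)
}

# Selector used by nested_performance: run the elimination schedule on the
# training fold only and keep the recorded set whose size fraction is
# closest to the globally selected fraction (ties toward the smaller set).
make_fraction_selector <- function(selected_fraction, n_trees = 500,
                                   mtry = NULL) {
  force(selected_fraction)
  function(train_fm, seed) {
    p <- ncol(train_fm$values)
    elim_seeds <- derive_seeds(seed, 64L)
    sets <- list(train_fm$peak_ids)
    current <- train_fm$peak_ids
    round <- 0L
    repeat {
      round <- round + 1L
      model <- fit_forest(fm_subset(train_fm, peak_ids = current),
                          n_trees = n_trees, mtry = mtry,
                          seed = elim_seeds[round], importance = TRUE)
      keep <- median_mda_keep(model$mda)
      if (sum(keep) < 2L || all(keep)) break
      current <- current[keep]
      sets <- c(sets, list(current))
    }
    frac <- lengths(sets) / p
    dev <- abs(frac - selected_fraction)
    sets[[max(which(dev == min(dev)))]]
  }
}

#' Nested cross-validated performance of the elimination-selected panel
#'
#' Calls [repeated_cv()] with a selector that reruns the median-MDA
#' elimination schedule inside every training fold and keeps the set whose
#' size fraction matches `selected_fraction` (the fraction selected by
#' [rfe()] on the full data). Because the per-fold selection never sees the
#' held-out samples, the pooled result is an unbiased generalization
#' estimate for a panel of that size. With `selected_fraction = NULL` the
#' selector is disabled and the result equals [repeated_cv()] exactly for
#' the same seed.
#'
#' @param features a `feature_matrix`.
#' @param selected_fraction panel size as a fraction of all features, e.g.
#'   `length(trace$selected_features) / ncol(features$values)`; `NULL`
#'   disables selection.
#' @param n_folds,n_repetitions,n_trees,mtry,seed as in [repeated_cv()].
#' @return a `cv_result`.
#' @export
nested_performance <- function(features, selected_fraction = NULL,
                               n_folds = 10, n_repetitions = 10,
                               n_trees = 500, mtry = NULL, seed = 1L) {
  selector <- if (is.null(selected_fraction)) NULL else
    make_fraction_selector(selected_fraction, n_trees = n_trees, mtry = mtry)
  repeated_cv(features, n_folds = n_folds, n_repetitions = n_repetitions,
              selector = selector, n_trees = n_trees, mtry = mtry,
              seed = seed)
}
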