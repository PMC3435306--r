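# Random Forest classification: out-of-bag vote fractions, mean decrease in
# accuracy (MDA) importance, major-vote class assignment, vote-fraction
# ROC/AUC, and repeated stratified k-fold cross-validation with optional
# in-fold feature selection.

# Accept either a feature_matrix or a bare matrix plus labels.
as_feature_input <- function(features, labels = NULL) {
  if (inherits(features, "feature_matrix")) {
    list(x = features$values, y = features$labels,
         ids = features$peak_ids, sample_ids = features$sample_ids)
  } else {
    x <- as.matrix(features)
    if (is.null(labels)) stop("labels required when features is a matrix")
    if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
    list(x = x, y = as.character(labels), ids = colnames(x),
         sample_ids = rownames(x) %||% as.character(seq_len(nrow(x))))
  }
}

check_two_classes <- function(y) {
  if (!all(y %in% c("case", "control"))) {
    stop("labels must be 'case' or 'control'")
  }
  if (length(unique(y)) < 2L) stop("both classes must be present")
}

#' Fit a Random Forest and expose its out-of-bag contract
#'
#' Grows an ensemble of `n_trees` classification trees on bootstrap samples
#' (tree induction is delegated to the \pkg{randomForest} package), and
#' exposes the quantities the profiling workflow consumes: the out-of-bag
#' (OOB) error under strict major vote, the per-training-sample OOB vote
#' fraction for the case class, and per-feature permutation importance as
#' raw mean decrease in accuracy (MDA) and as a z-score (mean per-tree
#' accuracy decrease divided by its standard error).
#'
#' @param features a `feature_matrix`, or a numeric matrix (samples x
#'   features) with `labels` supplied separately.
#' @param labels optional character vector (`"case"`/`"control"`) when
#'   `features` is a matrix.
#' @param n_trees number of trees (default 500).
#' @param mtry features tried per split; default `floor(sqrt(p))`.
#' @param seed integer seed; the fit is deterministic given it.
#' @param importance compute permutation importance (default `TRUE`; skip
#'   for speed when only votes are needed).
#' @return an object of class `forest_model` with elements `n_trees`,
#'   `oob_error`, `votes` (named case-vote fractions), `mda`, `mda_z`,
#'   `feature_ids`, `labels`, and the underlying `rf` fit.
#' @export
fit_forest <- function(features, labels = NULL, n_trees = 500, mtry = NULL,
                       seed = 1L, importance = TRUE) {
  inp <- as_feature_input(features, labels)
  check_two_classes(inp$y)
  if (ncol(inp$x) < 1L) stop("at least one feature required")
  if (min(table(inp$y)) < 2L) stop("at least 2 samples per class required")
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(inp$x))))
  y <- factor(inp$y, levels = c("control", "case"))
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(
    x = inp$x, y = y, ntree = n_trees, mtry = mtry,
    importance = importance, replace = TRUE
  )
  votes <- rf$votes[, "case"]
  names(votes) <- inp$sample_ids
  oob_error <- mean(major_vote(votes) != inp$y)
  if (importance) {
    mda <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1L]
    sdv <- rf$importanceSD[, "MeanDecreaseAccuracy"]
    mda_z <- ifelse(sdv > 0, mda / sdv, 0)
  } else {
    mda <- mda_z <- NULL
  }
  structure(
    list(rf = rf, n_trees = n_trees, mtry = mtry, oob_error = oob_error,
         votes = votes, mda = mda, mda_z = mda_z,
         feature_ids = inp$ids, labels = inp$y, seed = as.integer(seed)),
    class = "forest_model"
  )
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf(
    "<forest_model> %d trees, mtry %d, %d feature(s), OOB error %.3f\n",
    x$n_trees, x$mtry, length(x$feature_ids), x$oob_error
  ))
  invisible(x)
}

#' Case-vote fractions for new samples
#'
#' @param object a `forest_model`.
#' @param newdata a `feature_matrix` or numeric matrix with the model's
#'   feature columns.
#' @param ... unused.
#' @return named numeric vector of case-vote fractions in \[0, 1\].
#' @export
predict.forest_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$values else
    as.matrix(newdata)
  x <- x[, object$feature_ids, drop = FALSE]
  p <- stats::predict(object$rf, x, type = "prob")[, "case"]
  stats::setNames(as.numeric(p), rownames(x))
}

#' Major-vote class assignment
#'
#' A sample is called `"case"` if and only if strictly more than half of
#' the trees vote for it; a fraction of exactly 0.5 is `"control"`.
#'
#' @param vote_fraction numeric vector of case-vote fractions in \[0, 1\].
#' @return character vector of `"case"` / `"control"`.
#' @export
#' @examples
#' major_vote(c(0.51, 0.5, 0))
major_vote <- function(vote_fraction) {
  vote_fraction <- as.numeric(vote_fraction)
  if (any(!is.finite(vote_fraction)) ||
      any(vote_fraction < 0 | vote_fraction > 1)) {
    stop("vote fractions must lie in [0, 1]")
  }
  ifelse(vote_fraction > 0.5, "case", "control")
}

#' Rank-based AUC from ensemble vote fractions
#'
#' The probability that a randomly chosen case receives a higher vote
#' fraction than a randomly chosen control, with ties counting one half:
#' `(concordant + 0.5 * tied) / (n_case * n_control)`.
#'
#' @param vote_fractions numeric scores (vote fractions).
#' @param labels character vector, `"case"` / `"control"`, both present.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' vote_auc(c(0.9, 0.4, 0.6, 0.1), c("case", "case", "control", "control"))
vote_auc <- function(vote_fractions, labels) {
  labels <- as.character(labels)
  if (length(vote_fractions) != length(labels)) stop("length mismatch")
  check_two_classes(labels)
  r <- rank(vote_fractions)
  n1 <- sum(labels == "case")
  n0 <- sum(labels == "control")
  (sum(r[labels == "case"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pooled accuracy, sensitivity and specificity under major vote
#'
#' Sensitivity is the fraction of case predictions that are correct among
#' all case samples, specificity the analogue for controls, accuracy the
#' overall fraction correct; all reported as percentages rounded to one
#' decimal.
#'
#' @param predictions character vector of predicted classes.
#' @param labels character vector of true classes, both classes present.
#' @return list with `accuracy`, `sensitivity`, `specificity` (percent, one
#'   decimal) and `counts` (named vector `tp`, `fn`, `tn`, `fp`,
#'   `n_correct`, `n_total`).
#' @export
#' @examples
#' # 448 of 580 correct -> 77.2% accuracy
confusion_metrics <- function(predictions, labels) {
  predictions <- as.character(predictions)
  labels <- as.character(labels)
  if (length(predictions) != length(labels)) stop("length mismatch")
  check_two_classes(labels)
  tp <- sum(predictions == "case" & labels == "case")
  fn <- sum(predictions == "control" & labels == "case")
  tn <- sum(predictions == "control" & labels == "control")
  fp <- sum(predictions == "case" & labels == "control")
  n <- length(labels)
  list(
    accuracy = round(100 * (tp + tn) / n, 1),
    sensitivity = round(100 * tp / (tp + fn), 1),
    specificity = round(100 * tn / (tn + fp), 1),
    counts = c(tp = tp, fn = fn, tn = tn, fp = fp,
               n_correct = tp + tn, n_total = n)
  )
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin into k folds. Returns an integer fold id per sample.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < 2L) {
      stop("each class needs at least 2 samples for stratified folds")
    }
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validation of the forest classifier
#'
#' Runs `n_repetitions` independent stratified `n_folds`-fold partitions,
#' so every sample is scored once per repetition (10 x 10 by default:
#' "each sample 10 times in the test set"). If a `selector` is supplied,
#' it is applied inside each training fold, using training data only, and
#' the held-out fold is scored on the selected features — keeping all
#' class-information-using selection steps inside the cross-validation.
#' Predictions are pooled over all repetitions: AUC on the pooled vote
#' fractions, accuracy/sensitivity/specificity on the pooled major-vote
#' predictions.
#'
#' @param features a `feature_matrix`.
#' @param n_folds folds per repetition (default 10).
#' @param n_repetitions repetitions (default 10).
#' @param selector optional `function(train_fm, seed)` returning the
#'   character ids of the features to keep.
#' @param n_trees,mtry forest parameters per fold.
#' @param seed master seed; repetition and fold seeds are derived from it.
#' @return an object of class `cv_result`: `predictions` (data frame with
#'   `repetition`, `sample_id`, `label`, `vote`, `predicted`), pooled
#'   `auc`, `accuracy`, `sensitivity`, `specificity`, `counts`, and the CV
#'   geometry.
#' @export
repeated_cv <- function(features, n_folds = 10, n_repetitions = 10,
                        selector = NULL, n_trees = 500, mtry = NULL,
                        seed = 1L) {
  stopifnot(inherits(features, "feature_matrix"))
  check_two_classes(features$labels)
  if (min(table(features$labels)) < 2L) {
    stop("at least 2 samples per class required")
  }
  rep_seeds <- derive_seeds(seed, n_repetitions)
  rows <- vector("list", n_repetitions)
  for (r in seq_len(n_repetitions)) {
    set.seed(rep_seeds[r])
    fold <- stratified_folds(features$labels, n_folds)
    fold_seeds <- matrix(sample.int(.seed_max, 2L * n_folds), nrow = 2L)
    preds <- vector("list", n_folds)
    for (f in seq_len(n_folds)) {
      test_idx <- which(fold == f)
      if (!length(test_idx)) next
      train_idx <- which(fold != f)
      train <- fm_subset(features, sample_idx = train_idx)
      if (length(unique(train$labels)) < 2L) {
        stop("training fold lost a class; use fewer folds")
      }
      keep <- if (is.null(selector)) train$peak_ids else
        selector(train, fold_seeds[1L, f])
      train <- fm_subset(train, peak_ids = keep)
      model <- fit_forest(train, n_trees = n_trees, mtry = mtry,
                          seed = fold_seeds[2L, f], importance = FALSE)
      test <- fm_subset(features, peak_ids = keep, sample_idx = test_idx)
      votes <- predict(model, test)
      preds[[f]] <- data.frame(
        repetition = r, sample_id = test$sample_ids, label = test$labels,
        vote = as.numeric(votes), stringsAsFactors = FALSE
      )
    }
    rows[[r]] <- do.call(rbind, preds)
  }
  pred <- do.call(rbind, rows)
  pred <- pred[order(pred$repetition, match(pred$sample_id,
                                            features$sample_ids)), ]
  rownames(pred) <- NULL
  pred$predicted <- major_vote(pred$vote)
  metrics <- confusion_metrics(pred$predicted, pred$label)
  structure(
    list(
      predictions = pred,
      auc = vote_auc(pred$vote, pred$label),
      accuracy = metrics$accuracy, sensitivity = metrics$sensitivity,
      specificity = metrics$specificity, counts = metrics$counts,
      n_folds = n_folds, n_repetitions = n_repetitions, seed = seed
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    paste0("<cv_result> %dx stratified %d-fold CV, %d pooled predictions\n",
           "  AUC %.3f | accuracy %.1f%% | sensitivity %.1f%% | ",
           "specificity %.1f%%\n"),
    x$n_repetitions, x$n_folds, nrow(x$predictions),
    x$auc, x$accuracy, x$sensitivity, x$specificity
  ))
  invisible(x)
}

#' ROC points from vote fractions
#'
#' One point per distinct cutoff, cutoffs descending from above the maximum
#' score to below the minimum; a sample is called a case when its score is
#' strictly greater than the cutoff. The trapezoidal area under the
#' returned points equals [vote_auc()].
#'
#' @param vote_fractions numeric scores.
#' @param labels `"case"` / `"control"`, both present.
#' @return data frame with columns `cutoff`, `fpr` (1 - specificity),
#'   `tpr` (sensitivity), starting at (0, 0) and ending at (1, 1).
#' @export
roc_points <- function(vote_fractions, labels) {
  labels <- as.character(labels)
  if (length(vote_fractions) != length(labels)) stop("length mismatch")
  check_two_classes(labels)
  n1 <- sum(labels == "case")
  n0 <- sum(labels == "control")
  cuts <- c(Inf, sort(unique(vote_fractions), decreasing = TRUE), -Inf)
  pts <- t(vapply(cuts, function(ct) {
    pos <- vote_fractions > ct
    c(fpr = sum(pos & labels == "control") / n0,
      tpr = sum(pos & labels == "case") / n1)
  }, numeric(2)))
  df <- data.frame(cutoff = cuts, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
  same <- c(FALSE, diff(df$fpr) == 0 & diff(df$tpr) == 0)
  df <- df[!same, , drop = FALSE]
  rownames(df) <- NULL
  df
}
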