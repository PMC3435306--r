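test_that("major vote is strict: exactly 50% is a control call", {
  expect_equal(major_vote(c(0.51, 0.5, 0)), c("case", "control", "control"))
  expect_equal(major_vote(1), "case")
  expect_error(major_vote(1.2), "\\[0, 1\\]")
  expect_error(major_vote(-0.1), "\\[0, 1\\]")
})

test_that("vote AUC matches pair concordance on worked examples", {
  expect_equal(
    vote_auc(c(0.9, 0.8, 0.2, 0.1),
             c("case", "case", "control", "control")),
    1
  )
  # 3 of 4 case/control pairs concordant
  expect_equal(
    vote_auc(c(0.9, 0.4, 0.6, 0.1),
             c("case", "case", "control", "control")),
    0.75
  )
  expect_equal(vote_auc(c(0.5, 0.5), c("case", "control")), 0.5)
  expect_error(vote_auc(c(0.1, 0.2), c("case", "case")), "both classes")
})

test_that("vote AUC equals brute-force concordance on random inputs", {
  set.seed(99)
  for (i in 1:25) {
    n1 <- sample(2:60, 1)
    n0 <- sample(2:60, 1)
    labels <- rep(c("case", "control"), c(n1, n0))
    # mix of continuous scores and heavy ties
    scores <- if (i %% 2 == 0) runif(n1 + n0) else
      sample(seq(0, 1, by = 0.1), n1 + n0, replace = TRUE)
    expect_equal(vote_auc(scores, labels), auc_bruteforce(scores, labels))
  }
})

test_that("confusion metrics reproduce the pooled percentage arithmetic", {
  labels <- rep(c("case", "control"), c(350, 230))
  predictions <- c(
    rep(c("case", "control"), c(273, 77)),    # 273/350 cases correct
    rep(c("control", "case"), c(175, 55))     # 175/230 controls correct
  )
  m <- confusion_metrics(predictions, labels)
  expect_equal(m$sensitivity, 78.0)
  expect_equal(m$specificity, 76.1)
  expect_equal(m$accuracy, 77.2)
  expect_equal(unname(m$counts[c("n_correct", "n_total")]), c(448L, 580L))
  expect_error(confusion_metrics("case", c("case", "control")), "length")
})

test_that("a perfectly separated feature drives OOB error to zero", {
  oob <- vapply(1:10, function(sd) {
    fm <- shifted_fm(20, 20, p = 1, n_marker = 1, delta = 50, seed = sd)
    fit_forest(fm, n_trees = 100, seed = sd)$oob_error
  }, numeric(1))
  expect_true(all(oob <= 0.05))
})

test_that("permuted labels give chance-level OOB error", {
  oob <- vapply(1:5, function(sd) {
    fm <- shifted_fm(20, 20, p = 1, n_marker = 1, delta = 50, seed = sd)
    set.seed(1000 + sd)
    fm_perm <- new_feature_matrix(fm$values, fm$sample_ids,
                                  sample(fm$labels), fm$peak_ids)
    fit_forest(fm_perm, n_trees = 100, seed = sd)$oob_error
  }, numeric(1))
  expect_gte(mean(oob), 0.35)
  expect_lte(mean(oob), 0.65)
})

test_that("an informative feature out-ranks pure noise by MDA z-score", {
  wins <- vapply(1:10, function(sd) {
    fm <- shifted_fm(25, 25, p = 5, n_marker = 1, delta = 2.5, seed = sd)
    model <- fit_forest(fm, n_trees = 200, seed = sd)
    which.max(model$mda_z) == 1L && model$mda_z[1L] > max(model$mda_z[-1L])
  }, logical(1))
  expect_gte(sum(wins), 9L)
})

test_that("forest fitting validates input and is seed-deterministic", {
  fm <- shifted_fm(10, 10, p = 3, seed = 2)
  one_class <- new_feature_matrix(fm$values, fm$sample_ids,
                                  rep("case", 20), fm$peak_ids)
  expect_error(fit_forest(one_class), "both classes")
  a <- fit_forest(fm, n_trees = 50, seed = 7)
  b <- fit_forest(fm, n_trees = 50, seed = 7)
  expect_identical(a$votes, b$votes)
  expect_identical(a$mda, b$mda)
})

test_that("repeated CV books every sample once per repetition", {
  fm <- shifted_fm(9, 7, p = 6, n_marker = 2, delta = 2, seed = 3)
  cv <- repeated_cv(fm, n_folds = 5, n_repetitions = 4, n_trees = 50,
                    seed = 11)
  expect_equal(nrow(cv$predictions), 16L * 4L)
  expect_equal(sum(cv$predictions$label == "case"), 9L * 4L)
  expect_equal(sum(cv$predictions$label == "control"), 7L * 4L)
  per_rep <- table(cv$predictions$repetition, cv$predictions$sample_id)
  expect_true(all(per_rep == 1L))
  # pooled accuracy is correct / total on the pooled predictions
  expect_equal(
    cv$accuracy,
    round(100 * mean(cv$predictions$predicted == cv$predictions$label), 1)
  )
  cv2 <- repeated_cv(fm, n_folds = 5, n_repetitions = 4, n_trees = 50,
                     seed = 11)
  expect_identical(cv$predictions, cv2$predictions)
})

test_that("repeated CV separates a strong signal and stays at chance under the null", {
  fm <- shifted_fm(12, 12, p = 4, n_marker = 2, delta = 6, seed = 5)
  cv <- repeated_cv(fm, n_folds = 5, n_repetitions = 3, n_trees = 100,
                    seed = 2)
  expect_gte(cv$auc, 0.99)

  null_auc <- vapply(1:5, function(sd) {
    fm0 <- shifted_fm(12, 12, p = 10, n_marker = 0, seed = 100 + sd)
    repeated_cv(fm0, n_folds = 5, n_repetitions = 3, n_trees = 50,
                seed = sd)$auc
  }, numeric(1))
  expect_gte(mean(null_auc), 0.4)
  expect_lte(mean(null_auc), 0.6)
})

test_that("ROC points trace the vote AUC and hit the corner cases", {
  set.seed(4)
  labels <- rep(c("case", "control"), c(30, 25))
  scores <- c(runif(30, 0.3, 1), runif(25, 0, 0.7))
  pts <- roc_points(scores, labels)
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  expect_equal(trapezoid_area(pts$fpr, pts$tpr), vote_auc(scores, labels),
               tolerance = 1e-12)

  perfect <- roc_points(c(0.9, 0.8, 0.2, 0.1),
                        c("case", "case", "control", "control"))
  expect_true(any(perfect$fpr == 0 & perfect$tpr == 1))

  tied <- roc_points(rep(0.4, 6), rep(c("case", "control"), 3))
  expect_equal(trapezoid_area(tied$fpr, tied$tpr), 0.5)
  expect_equal(nrow(tied), 2L)
})

test_that("vote AUC agrees with an established ROC implementation", {
  set.seed(123)
  labels <- rep(c("case", "control"), c(40, 30))
  scores <- c(rnorm(40, 1), rnorm(30))
  expect_equal(
    vote_auc(scores, labels),
    as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores, levels = c("control", "case"),
      direction = "<", quiet = TRUE
    )))
  )
})
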