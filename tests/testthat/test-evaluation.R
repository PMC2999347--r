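test_that("confusion counts fill the four cells correctly", {
  truth <- rep(c(1, 0), c(6, 4))
  perfect <- confusion(truth, truth)
  expect_identical(unclass(perfect)[c("TP", "TN", "FP", "FN")],
                   list(TP = 6L, TN = 4L, FP = 0L, FN = 0L))
  allpos <- confusion(rep(1, 10), truth)
  expect_identical(c(allpos$TP, allpos$FP, allpos$TN, allpos$FN),
                   c(6L, 4L, 0L, 0L))
  # swapping the arguments transposes FP and FN
  pred <- c(rep(1, 8), 0, 0)
  a <- confusion(pred, truth)
  b <- confusion(truth, pred)
  expect_identical(c(a$FP, a$FN), c(b$FN, b$FP))
  expect_error(confusion(1, c(1, 0)), "lengths differ")
})

test_that("accuracy, sensitivity, specificity and MCC follow their formulas", {
  perfect <- classification_metrics(confusion(rep(c(1, 0), c(6, 4)),
                                              rep(c(1, 0), c(6, 4))))
  expect_equal(as.numeric(perfect),
               c(100, 100, 100, 1), tolerance = 1e-12)

  # TP=3, TN=2, FP=1, FN=1 worked by hand
  m <- classification_metrics(
    confusion(c(1, 1, 1, 1, 0, 0, 0), c(1, 1, 1, 0, 1, 0, 0)))
  expect_equal(as.numeric(m),
               c(100 * 5 / 7, 75, 100 * 2 / 3, 5 / 12), tolerance = 1e-12)

  allpos <- classification_metrics(confusion(rep(1, 10),
                                             rep(c(1, 0), c(6, 4))))
  expect_identical(unname(allpos[["specificity"]]), 0)
  # TN + FP > 0 here, so only the MCC denominator degenerates
  expect_identical(attr(allpos, "degenerate"), "mcc")
})

test_that("label-independent predictions give near-zero MCC", {
  set.seed(61)
  pred <- rbinom(10000, 1, 0.5)
  truth <- rbinom(10000, 1, 0.5)
  m <- classification_metrics(confusion(pred, truth))
  expect_lt(abs(m[["mcc"]]), 0.05)
})

test_that("ROC limits: separation gives AUC 1, constants 0.5", {
  truth <- rep(c(1, 0), each = 10)
  sep <- roc_curve(c(rnorm(10, 5), rnorm(10, -5)), truth)
  expect_identical(sep$auc, 1)
  expect_identical(sep$points$fpr[1], 0)
  expect_identical(sep$points$tpr[nrow(sep$points)], 1)
  expect_true(all(diff(sep$points$fpr) >= 0),
              all(diff(sep$points$tpr) >= 0))
  flat <- roc_curve(rep(0.3, 20), truth)
  expect_identical(flat$auc, 0.5)
  expect_error(roc_curve(rnorm(5), rep(1, 5)), "both classes")
})

test_that("threshold-sweep AUC equals the rank formulation exactly", {
  set.seed(62)
  for (i in 1:10) {
    truth <- rbinom(300, 1, 0.4)
    if (length(unique(truth)) < 2) next
    scores <- rnorm(300)
    if (i %% 2 == 0) scores <- round(scores, 1)  # force ties
    expect_equal(roc_curve(scores, truth)$auc,
                 sirnaforest:::auc_rank(scores, truth),
                 tolerance = 1e-10)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(63)
  truth <- rbinom(500, 1, 0.5)
  scores <- round(rnorm(500) + truth, 1)
  expect_equal(roc_curve(scores, truth)$auc,
               as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                              direction = "<",
                                              levels = c(0, 1)))),
               tolerance = 1e-10)
})

test_that("label swap with negated scores leaves AUC invariant", {
  set.seed(64)
  truth <- rbinom(200, 1, 0.5)
  scores <- rnorm(200) + 0.8 * truth
  a <- roc_curve(scores, truth)$auc
  b <- roc_curve(-scores, 1 - truth)$auc
  expect_equal(a, b, tolerance = 1e-12)
  expect_equal(roc_curve(-scores, truth)$auc, 1 - a, tolerance = 1e-12)
})

test_that("score-efficacy correlation is signed by inhibition", {
  lv <- c(0.1, 0.4, 0.5, 0.8, 0.95)
  expect_equal(score_efficacy_correlation(1 - lv, lv), 1, tolerance = 1e-12)
  expect_equal(score_efficacy_correlation(lv - 1, lv), -1,
               tolerance = 1e-12)
  expect_error(score_efficacy_correlation(c(1, 1, 1), lv[1:3]),
               "zero variance")
  expect_error(score_efficacy_correlation(1:2, lv[1:2]), "at least 3")
})

test_that("cross-validation partitions each class into balanced folds", {
  sim <- simulate_sirna(generator_config(n = 103, seed = 65))
  tab <- extract_table(sim$dataset)
  cv <- cross_validate(tab, n_folds = 5, seed = 66)
  fold <- cv$fold_assignment
  expect_identical(length(fold), 103L)
  expect_identical(sort(unique(fold)), 1:5)
  y <- attr(tab, "labels")
  for (cl in levels(y)) {
    sizes <- table(fold[y == cl])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  # pooled predictions carry one score per instance
  expect_identical(nrow(cv$predictions), 103L)
  expect_false(anyNA(cv$predictions$score))
})

test_that("cross-validation recovers a strongly separated scenario", {
  # classifier restricted to the trinucleotide-composition group, the
  # group carrying the planted signal
  trimers <- feature_schema()$names[feature_schema()$groups$trimer]
  aucs <- vapply(1:3, function(s) {
    sim <- simulate_sirna(separated_config(n = 200, seed = 600 + s))
    tab <- extract_table(sim$dataset)
    cv <- cross_validate(tab,
                         config = svm_config(feature_subset = trimers),
                         seed = s)
    cv$auc
  }, numeric(1L))
  expect_gt(median(aucs), 0.9)
})

test_that("pooled classifier output correlates positively with knockdown", {
  trimers <- feature_schema()$names[feature_schema()$groups$trimer]
  rs <- vapply(1:5, function(s) {
    sim <- simulate_sirna(generator_config(n = 200, seed = 700 + s))
    tab <- extract_table(sim$dataset)
    cross_validate(tab, config = svm_config(feature_subset = trimers),
                   seed = s)$score_efficacy_r
  }, numeric(1L))
  expect_true(all(rs > 0))
})

test_that("a class smaller than the fold count is rejected", {
  set.seed(67)
  X <- matrix(runif(20 * 3), 20, 3)
  y <- rep(c("negative", "positive"), c(17, 3))
  expect_error(cross_validate(X, y, n_folds = 5), "fewer members")
})
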