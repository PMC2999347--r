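# Shared small fixture: one perfectly separating feature among noise.
planted_data <- function(n = 60L, p = 6L, seed = 41L) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- rep(c(0L, 1L), length.out = n)
  X[, 1L] <- y + runif(n, -0.2, 0.2)
  list(X = X, y = y)
}

test_that("a separating feature yields a pure tree on its bootstrap", {
  d <- planted_data()
  bs <- sample(seq_len(nrow(d$X)), replace = TRUE)
  tree <- fit_tree(d$X, d$y, bootstrap = bs, m = ncol(d$X), seed = 5)
  pred <- predict(tree, d$X[bs, , drop = FALSE])
  expect_identical(as.integer(pred == "positive"), d$y[bs])
})

test_that("constant features give a single majority leaf", {
  X <- matrix(1, 30, 3)
  y <- rep(c(0L, 1L), c(10L, 20L))
  tree <- fit_tree(X, y, m = 3, seed = 1)
  expect_identical(tree$tree$feature, -1L)
  expect_identical(as.character(unique(predict(tree, X))), "positive")
})

test_that("tree fitting is deterministic under a fixed seed", {
  d <- planted_data(p = 10)
  t1 <- fit_tree(d$X, d$y, m = 3, seed = 99)
  t2 <- fit_tree(d$X, d$y, m = 3, seed = 99)
  expect_identical(t1$tree, t2$tree)
})

test_that("forests vote over seeded bootstraps, reproducibly", {
  d <- planted_data(n = 40)
  f1 <- fit_forest(d$X, d$y, forest_config(n_trees = 25, m = 2, seed = 7))
  f2 <- fit_forest(d$X, d$y, forest_config(n_trees = 25, m = 2, seed = 7))
  expect_identical(predict(f1, d$X, type = "votes"),
                   predict(f2, d$X, type = "votes"))

  single <- fit_forest(d$X, d$y, forest_config(n_trees = 1, m = 2, seed = 3))
  tree_pred <- ifelse(
    sirnaforest:::cpp_forest_votes(single$trees, d$X)[, 2] > 0,
    "positive", "negative")
  expect_identical(as.character(predict(single, d$X)), tree_pred)

  expect_error(
    fit_forest(d$X, d$y, forest_config(n_trees = 5, m = 99, seed = 1)),
    "config error")
})

test_that("out-of-bag sets average about a third of the data", {
  d <- planted_data(n = 280, p = 4)
  f <- fit_forest(d$X, d$y, forest_config(n_trees = 300, m = 2, seed = 11))
  oob_sizes <- colSums(f$inbag == 0L)
  expect_gte(mean(oob_sizes), 0.33 * 280)
  expect_lte(mean(oob_sizes), 0.41 * 280)
})

test_that("features unused by every tree score exactly zero importance", {
  d <- planted_data(n = 50, p = 3)
  X <- cbind(d$X, const1 = 0.5, const2 = 1)  # unsplittable columns
  f <- fit_forest(X, d$y, forest_config(n_trees = 30, m = 5, seed = 13))
  used <- sirnaforest:::cpp_used_features(f$trees, ncol(X))
  expect_false(any(used[4:5]))
  imp <- oob_permutation_importance(f, X)
  expect_identical(imp$raw_score[4:5], c(0, 0))
  expect_identical(imp$z_score[4:5], c(0, 0))
})

test_that("raw importance is invariant to a class-encoding swap", {
  d <- planted_data(n = 50, p = 4)
  cfg <- forest_config(n_trees = 40, m = 4, seed = 17)  # m = p: no tie leaves
  f1 <- fit_forest(d$X, d$y, cfg)
  f2 <- fit_forest(d$X, 1L - d$y, cfg)
  i1 <- oob_permutation_importance(f1, d$X, seed = 4)
  i2 <- oob_permutation_importance(f2, d$X, 1L - d$y, seed = 4)
  expect_identical(i1$raw_score, i2$raw_score)
})

test_that("a planted predictive feature dominates the importance ranking", {
  d <- planted_data(n = 120, p = 8, seed = 43)
  f <- fit_forest(d$X, d$y, forest_config(n_trees = 100, m = 3, seed = 19))
  imp <- oob_permutation_importance(f, d$X)
  expect_identical(top_k_by_z(imp, 1), "f1")
  expect_gt(imp$z_score[1], max(imp$z_score[-1]))
})

test_that("top-k ranking breaks ties by schema order", {
  imp <- data.frame(feature = c("a", "b", "c", "d"),
                    raw_score = c(2, 1, 1, 0), se = 1,
                    z_score = c(2, 1, 1, 0))
  class(imp) <- c("feature_importance", "data.frame")
  expect_identical(top_k_by_z(imp, 2), c("a", "b"))
  expect_identical(top_k_by_z(imp, 4), c("a", "b", "c", "d"))
  expect_error(top_k_by_z(imp, 5), "exceeds")
})

test_that("a single-forest consensus reduces to that forest's top-k", {
  d <- planted_data(n = 60, p = 8)
  sel <- consensus_select(d$X, d$y, m_values = 3L, B = 50, k = 4,
                          min_count = 1L, seed = 23)
  seeds <- sirnaforest:::derive_seeds(23L, 2L)
  f <- fit_forest(d$X, d$y,
                  forest_config(n_trees = 50, m = 3, seed = seeds[1]))
  imp <- oob_permutation_importance(f, d$X, seed = seeds[2])
  expect_setequal(sel$per_forest_topk[[1]], top_k_by_z(imp, 4))
  expect_setequal(sel$selected, top_k_by_z(imp, 4))
})

test_that("with min_count = 1 the selection is the union of top-k sets", {
  d <- planted_data(n = 60, p = 8)
  sel <- consensus_select(d$X, d$y, m_values = c(2L, 4L, 6L), B = 40,
                          k = 3, min_count = 1L, seed = 29)
  expect_setequal(sel$selected,
                  unique(unlist(sel$per_forest_topk)))
  expect_true(all(lengths(sel$per_forest_topk) == 3L))
  expect_error(consensus_select(d$X, d$y, m_values = 2L, min_count = 2L),
               "min_count")
})

test_that("oob error does not grow as the forest gets larger", {
  errs <- vapply(1:10, function(s) {
    sim <- simulate_sirna(separated_config(n = 120, seed = 500 + s))
    tab <- extract_table(sim$dataset)
    e <- vapply(c(10L, 200L), function(B) {
      f <- fit_forest(tab, config = forest_config(n_trees = B, m = 11,
                                                  seed = s))
      oob_predictions(f, tab)$error
    }, numeric(1L))
    e
  }, numeric(2L))
  expect_lte(mean(errs[2, ]), mean(errs[1, ]) + 0.01)
})
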