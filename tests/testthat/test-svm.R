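test_that("the RBF kernel matches its closed form and bounds", {
  expect_identical(rbf_kernel(c(1, 2, 3), c(1, 2, 3), gamma = 0.7), 1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 0), gamma = 1), exp(-1),
               tolerance = 1e-12)
  d <- seq(0.1, 3, by = 0.1)
  k <- vapply(d, function(di) rbf_kernel(0, di, gamma = 1.2), numeric(1))
  expect_true(all(diff(k) < 0))
  expect_true(all(k > 0 & k <= 1))
  expect_error(rbf_kernel(1:2, 1:3, gamma = 1), "dimension")
  expect_error(rbf_kernel(1, 1, gamma = 0), "gamma")
})

test_that("kernel matrices are symmetric positive semi-definite", {
  set.seed(51)
  for (i in 1:3) {
    X <- matrix(rnorm(50 * 4), 50, 4)
    K <- rbf_kernel_matrix(X, X, gamma = 1.2)
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_gte(min(eigen(K, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
  }
})

test_that("well-separated blobs are fit exactly at large C", {
  b <- make_blobs(n_per_class = 20, sep = 4, seed = 52)
  model <- train_svm(b$X, b$y, svm_config(gamma = 1.2, C = 10))
  expect_identical(predict(model, b$X), b$y)
  nsv <- nrow(model$support_vectors)
  expect_gt(nsv, 0)
  expect_lte(nsv, nrow(b$X))
  expect_error(train_svm(b$X, rep("positive", nrow(b$X))), "both classes")
})

test_that("stored expansion reproduces the solver's decision values", {
  b <- make_blobs(n_per_class = 25, sep = 1.5, sd = 1, seed = 53)
  cfg <- svm_config(gamma = 0.8, C = 1.2)
  model <- train_svm(b$X, b$y, cfg)
  mine <- decision_values(model, b$X)
  Xs <- sirnaforest:::apply_scaling(b$X, model$scaling)
  theirs <- attr(predict(model$libsvm, Xs, decision.values = TRUE),
                 "decision.values")
  # orientation-free comparison against libsvm
  expect_equal(abs(mine), abs(as.numeric(theirs)), tolerance = 1e-8)
  # orientation: positives should score higher on average
  expect_gt(mean(mine[b$y == "positive"]), mean(mine[b$y == "negative"]))
})

test_that("unbounded support vectors sit on the unit margin", {
  b <- make_blobs(n_per_class = 30, sep = 2, sd = 1, seed = 54)
  model <- train_svm(b$X, b$y, svm_config(gamma = 0.5, C = 1.2))
  free <- abs(model$dual_coefs) < 1.2 - 1e-4
  expect_true(any(free))
  # evaluate on the original (unscaled) rows that became support vectors
  f_sv <- decision_values(model, b$X[model$libsvm$index, , drop = FALSE])
  expect_equal(abs(f_sv[free]), rep(1, sum(free)), tolerance = 1e-2)
})

test_that("duplicating the training set leaves the decision unchanged", {
  # hard-margin regime: every alpha interior, so doubling each point
  # cannot move the optimum
  b <- make_blobs(n_per_class = 10, sep = 3, seed = 55)
  m1 <- train_svm(b$X, b$y, svm_config(C = 10))
  m2 <- train_svm(rbind(b$X, b$X), c(b$y, b$y), svm_config(C = 10))
  expect_equal(decision_values(m1, b$X), decision_values(m2, b$X),
               tolerance = 1e-3)
})

test_that("decision values are row-order invariant and name-checked", {
  b <- make_blobs(seed = 56)
  model <- train_svm(b$X, b$y, svm_config())
  perm <- sample(nrow(b$X))
  expect_equal(decision_values(model, b$X)[perm],
               decision_values(model, b$X[perm, ]), tolerance = 1e-12)
  X2 <- b$X
  colnames(X2) <- c("f1", "other")
  expect_error(decision_values(model, X2), "f2")
})

test_that("feature subsetting is honored and missing columns reported", {
  set.seed(57)
  X <- matrix(runif(40 * 5), 40, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- rep(c("negative", "positive"), 20)
  model <- train_svm(X, y, svm_config(feature_subset = c("f2", "f4")))
  expect_identical(model$features, c("f2", "f4"))
  expect_error(train_svm(X, y, svm_config(feature_subset = "nope")),
               "nope")
})

test_that("free-energy-like columns are min-max scaled, others passed", {
  set.seed(58)
  X <- cbind(freq = runif(30), MFE = -runif(30, 0, 8))
  y <- rep(c("negative", "positive"), 15)
  model <- train_svm(X, y, svm_config())
  sc <- model$scaling
  expect_identical(unname(sc$lo[1]), 0)
  expect_identical(unname(sc$hi[1]), 1)
  expect_identical(unname(sc$lo[2]), min(X[, 2]))
  expect_identical(unname(sc$hi[2]), max(X[, 2]))
})

test_that("models survive JSON serialization round-trips", {
  b <- make_blobs(seed = 59)
  model <- train_svm(b$X, b$y, svm_config(gamma = 2.4, C = 0.6))
  path <- tempfile(fileext = ".json")
  write_svm_model(model, path)
  back <- read_svm_model(path)
  expect_equal(decision_values(back, b$X), decision_values(model, b$X),
               tolerance = 1e-10)
  expect_identical(back$config$gamma, 2.4)
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), bad)
  expect_error(read_svm_model(bad), "model file")
})
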