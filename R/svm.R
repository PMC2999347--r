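#' SVM configuration
#'
#' @param gamma RBF kernel width (> 0); default 1.2, the best-performing
#'   setting of the reference protocol.
#' @param C Soft-margin regularization (> 0); default 1.2.
#' @param feature_subset Optional ordered character vector of feature
#'   names to train on (e.g. a consensus selection); `NULL` uses all
#'   columns.
#' @return An `svm_config`.
#' @export
svm_config <- function(gamma = 1.2, C = 1.2, feature_subset = NULL) {
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0")
  if (!is.numeric(C) || C <= 0) stop("C must be > 0")
  structure(list(gamma = gamma, C = C, feature_subset = feature_subset),
            class = "svm_config")
}

#' Radial basis function kernel
#'
#' `exp(-gamma * ||x - y||^2)`, in `(0, 1]`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param gamma Kernel width (> 0).
#' @return Kernel value.
#' @examples
#' rbf_kernel(c(0, 0), c(1, 0), gamma = 1)  # exp(-1)
#' @export
rbf_kernel <- function(x, y, gamma) {
  if (length(x) != length(y)) stop("x and y must have the same dimension")
  if (gamma <= 0) stop("gamma must be > 0")
  exp(-gamma * sum((x - y)^2))
}

#' RBF kernel matrix between row sets
#'
#' @param X,Y Numeric matrices with the same number of columns.
#' @param gamma Kernel width (> 0).
#' @return `nrow(X)` x `nrow(Y)` kernel matrix.
#' @export
rbf_kernel_matrix <- function(X, Y, gamma) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("X and Y must have the same dimension")
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  exp(-gamma * pmax(d2, 0))
}

# Fit the per-feature affine scaling used at train and predict time:
# features already in [0, 1] (all composition/positional/GC features) pass
# through unchanged; any feature whose training range leaves [0, 1]
# (the free-energy feature) is min-max scaled with training-set bounds.
fit_scaling <- function(X) {
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  needs <- lo < 0 | hi > 1
  lo[!needs] <- 0
  hi[!needs] <- 1
  hi[hi == lo] <- lo[hi == lo] + 1  # constant column -> maps to 0
  list(lo = lo, hi = hi)
}

apply_scaling <- function(X, scaling) {
  sweep(sweep(X, 2L, scaling$lo, "-"), 2L,
        scaling$hi - scaling$lo, "/")
}

svm_design <- function(X, feature_subset) {
  X <- unclass(X); attr(X, "labels") <- NULL; attr(X, "levels") <- NULL
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!is.null(feature_subset)) {
    missing_cols <- setdiff(feature_subset, colnames(X))
    if (length(missing_cols) > 0L) {
      stop("missing feature column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    X <- X[, feature_subset, drop = FALSE]
  }
  X
}

#' Train the RBF-kernel soft-margin SVM
#'
#' Solves the standard soft-margin dual with the RBF kernel (quadratic
#' optimization delegated to libsvm via \pkg{e1071}). The fitted model
#' stores the support vectors, dual coefficients and bias of the decision
#' function \eqn{f(x) = \sum_i \alpha_i y_i K(s_i, x) + b}, oriented so
#' that `f(x) > 0` predicts a potent siRNA, together with the feature
#' scaling fitted on the training data.
#'
#' @param X Feature matrix or `feature_table`.
#' @param y Labels; taken from the table attribute when omitted.
#' @param config An [svm_config()].
#' @return A `sirna_svm`.
#' @export
train_svm <- function(X, y = NULL, config = svm_config()) {
  stopifnot(inherits(config, "svm_config"))
  if (inherits(X, "feature_table") && is.null(y)) y <- attr(X, "labels")
  if (is.null(y)) stop("labels are required")
  y <- as_label_factor(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  Xd <- svm_design(X, config$feature_subset)
  if (any(!is.finite(Xd))) stop("feature matrix contains non-finite values")
  scaling <- fit_scaling(Xd)
  Xs <- apply_scaling(Xd, scaling)

  fit <- e1071::svm(x = Xs, y = y, scale = FALSE, kernel = "radial",
                    gamma = config$gamma, cost = config$C)
  # libsvm orients its decision value toward whichever class it saw first;
  # normalize so positive decision values mean the potent class.
  dv <- attr(predict(fit, Xs[1:2, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  flip <- if (startsWith(colnames(dv)[1L], "positive")) 1 else -1

  structure(list(
    support_vectors = fit$SV,
    dual_coefs = flip * as.numeric(fit$coefs),
    bias = -flip * fit$rho,
    config = config,
    scaling = scaling,
    features = colnames(Xs),
    n_train = nrow(Xs),
    libsvm = fit,
    version = "1"), class = "sirna_svm")
}

#' @export
print.sirna_svm <- function(x, ...) {
  cat(sprintf(
    "RBF-kernel SVM: gamma = %g, C = %g, %d features, %d support vectors\n",
    x$config$gamma, x$config$C, length(x$features),
    nrow(x$support_vectors)))
  invisible(x)
}

#' SVM decision values
#'
#' Evaluates the stored support-vector expansion
#' \eqn{f(x) = \sum_i \alpha_i y_i K(s_i, x) + b} for each row, after
#' applying the training-time feature scaling. Positive values predict
#' potent; the continuous value is what ROC construction thresholds and
#' what is correlated with knockdown efficacy.
#'
#' @param model A `sirna_svm`.
#' @param X Matrix containing the model's feature columns (by name when
#'   column names are present).
#' @return Numeric decision value per row.
#' @export
decision_values <- function(model, X) {
  stopifnot(inherits(model, "sirna_svm"))
  X <- unclass(X); attr(X, "labels") <- NULL; attr(X, "levels") <- NULL
  X <- as.matrix(X)
  if (!is.null(colnames(X))) {
    missing_cols <- setdiff(model$features, colnames(X))
    if (length(missing_cols) > 0L) {
      stop("missing feature column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    X <- X[, model$features, drop = FALSE]
  } else if (ncol(X) != length(model$features)) {
    stop("X has ", ncol(X), " columns; model expects ",
         length(model$features))
  }
  Xs <- apply_scaling(X, model$scaling)
  K <- rbf_kernel_matrix(Xs, model$support_vectors, model$config$gamma)
  as.numeric(K %*% model$dual_coefs + model$bias)
}

#' @export
predict.sirna_svm <- function(object, X, ...) {
  f <- decision_values(object, X)
  factor(ifelse(f > 0, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Serialize / restore an SVM model
#'
#' The model is written as a single versioned JSON file holding the
#' configuration, feature names, scaling bounds, support vectors, dual
#' coefficients and bias — everything [decision_values()] needs, so a
#' restored model predicts without refitting.
#'
#' @param model A `sirna_svm`.
#' @param path File path.
#' @return `write_svm_model`: `path` invisibly; `read_svm_model`: the
#'   restored `sirna_svm`.
#' @export
write_svm_model <- function(model, path) {
  stopifnot(inherits(model, "sirna_svm"))
  obj <- list(
    format = "sirnaforest-svm",
    version = model$version,
    gamma = model$config$gamma,
    C = model$config$C,
    features = model$features,
    scaling = list(lo = as.numeric(model$scaling$lo),
                   hi = as.numeric(model$scaling$hi)),
    support_vectors = unname(as.matrix(model$support_vectors)),
    dual_coefs = model$dual_coefs,
    bias = model$bias,
    n_train = model$n_train)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_svm_model
#' @export
read_svm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "sirnaforest-svm")) {
    stop("not a sirnaforest SVM model file: ", path)
  }
  sv <- as.matrix(obj$support_vectors)
  colnames(sv) <- obj$features
  structure(list(
    support_vectors = sv,
    dual_coefs = as.numeric(obj$dual_coefs),
    bias = obj$bias,
    config = svm_config(gamma = obj$gamma, C = obj$C,
                        feature_subset = obj$features),
    scaling = list(lo = stats::setNames(obj$scaling$lo, obj$features),
                   hi = stats::setNames(obj$scaling$hi, obj$features)),
    features = obj$features,
    n_train = obj$n_train,
    libsvm = NULL,
    version = obj$version), class = "sirna_svm")
}

#' Grid search of SVM parameters by cross-validated AUC
#'
#' @param X Feature matrix or `feature_table`.
#' @param y Labels; taken from the table attribute when omitted.
#' @param gammas,Cs Candidate grids (default `{0.1, 0.3, 0.6, 1.2, 2.4,
#'   4.8}` each).
#' @param feature_subset Optional feature names to restrict to.
#' @param n_folds Folds (default 5).
#' @param seed Fold-assignment seed.
#' @return List with `best` (an `svm_config`), `auc` of the best cell and
#'   the full `grid` data frame.
#' @export
tune_svm <- function(X, y = NULL,
                     gammas = c(0.1, 0.3, 0.6, 1.2, 2.4, 4.8),
                     Cs = c(0.1, 0.3, 0.6, 1.2, 2.4, 4.8),
                     feature_subset = NULL, n_folds = 5L, seed = 1L) {
  grid <- expand.grid(gamma = gammas, C = Cs)
  grid$auc <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- svm_config(grid$gamma[i], grid$C[i], feature_subset)
    cross_validate(X, y, config = cfg, n_folds = n_folds,
                   seed = seed)$auc
  }, numeric(1L))
  best <- which.max(grid$auc)
  list(best = svm_config(grid$gamma[best], grid$C[best], feature_subset),
       auc = grid$auc[best], grid = grid)
}
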