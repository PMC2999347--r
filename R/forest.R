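#' Random-forest configuration
#'
#' @param n_trees Number of trees `B` (default 1000, the full-protocol
#'   setting; tests typically use fewer for runtime).
#' @param m Number of candidate features sampled (without replacement) at
#'   each tree node.
#' @param seed Master seed; per-tree bootstrap/growing streams are derived
#'   from it deterministically.
#' @return A `forest_config`.
#' @export
forest_config <- function(n_trees = 1000L, m, seed = 1L) {
  n_trees <- as.integer(n_trees)
  m <- as.integer(m)
  if (n_trees < 1L) stop("n_trees must be >= 1")
  if (m < 1L) stop("m must be >= 1")
  structure(list(n_trees = n_trees, m = m, seed = as.integer(seed)),
            class = "forest_config")
}

# Coerce a feature_table / matrix + labels into the internal (X, y01) pair.
forest_xy <- function(X, y = NULL) {
  if (inherits(X, "feature_table") && is.null(y)) y <- attr(X, "labels")
  if (is.null(y)) stop("labels are required (supply y or a feature_table)")
  y <- as_label_factor(y)
  X <- unclass(X)
  attr(X, "labels") <- NULL
  attr(X, "levels") <- NULL
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("feature matrix contains non-finite values")
  list(X = X, y01 = as.integer(y == "positive"), y = y)
}

#' Fit a single classification tree
#'
#' Grows one CART tree (binary threshold splits chosen by Gini impurity
#' decrease among `m` features sampled uniformly without replacement at
#' each node; nodes split until pure or unsplittable; leaves predict the
#' majority class, ties resolving to negative) on an explicit bootstrap
#' multiset of row indices.
#'
#' @param X Feature matrix (rows = instances).
#' @param y Labels (`positive`/`negative`, logical or 0/1).
#' @param bootstrap Integer vector of 1-based row indices (duplicates
#'   allowed); defaults to all rows.
#' @param m Features sampled per node.
#' @param seed Integer seed for the node-sampling stream.
#' @return A `sirna_tree`.
#' @export
fit_tree <- function(X, y = NULL, bootstrap = NULL, m, seed = 1L) {
  d <- forest_xy(X, y)
  if (nrow(d$X) < 2L) stop("need at least 2 rows")
  m <- as.integer(m)
  if (m < 1L || m > ncol(d$X)) stop("m must be in 1..n_features")
  if (is.null(bootstrap)) bootstrap <- seq_len(nrow(d$X))
  bootstrap <- as.integer(bootstrap)
  if (any(bootstrap < 1L | bootstrap > nrow(d$X))) {
    stop("bootstrap indices out of range")
  }
  tree <- cpp_fit_tree(d$X, d$y01, bootstrap, m, as.integer(seed))
  structure(list(tree = tree, feature_names = colnames(d$X),
                 m = m, seed = as.integer(seed)),
            class = "sirna_tree")
}

#' @export
predict.sirna_tree <- function(object, X, ...) {
  X <- forest_xy(X, y = rep("negative", nrow(X)))$X  # labels unused
  votes <- cpp_forest_votes(list(object$tree), X)
  factor(ifelse(votes[, 2L] > votes[, 1L], "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Fit a random forest
#'
#' Grows `n_trees` CART trees, each on an independent seeded bootstrap
#' sample of size `n` drawn with replacement; the rows absent from a
#' tree's bootstrap form its out-of-bag (oob) set (about one third of the
#' data in expectation) and are recorded for importance scoring.
#' Forest prediction is the majority vote over trees (ties to negative).
#'
#' @param X Feature matrix or `feature_table`.
#' @param y Labels; taken from the table attribute when omitted.
#' @param config A [forest_config()].
#' @return A `sirna_forest`.
#' @export
fit_forest <- function(X, y = NULL, config) {
  stopifnot(inherits(config, "forest_config"))
  d <- forest_xy(X, y)
  n <- nrow(d$X)
  if (n < 10L) stop("need at least 10 instances")
  if (length(unique(d$y01)) < 2L) stop("both classes must be present")
  if (config$m > ncol(d$X)) {
    stop("config error: m (", config$m, ") exceeds n_features (",
         ncol(d$X), ")")
  }
  tree_seeds <- derive_seeds(config$seed, config$n_trees)
  fit <- cpp_fit_forest(d$X, d$y01, config$n_trees, config$m, tree_seeds)
  structure(list(trees = fit$trees, inbag = fit$inbag, config = config,
                 n = n, p = ncol(d$X), feature_names = colnames(d$X),
                 y = d$y),
            class = "sirna_forest")
}

#' @export
print.sirna_forest <- function(x, ...) {
  cat(sprintf("random forest: %d trees, m = %d, n = %d, p = %d (seed %d)\n",
              x$config$n_trees, x$config$m, x$n, x$p, x$config$seed))
  invisible(x)
}

#' Predict with a random forest
#'
#' @param object A `sirna_forest`.
#' @param X Feature matrix with the training columns.
#' @param type `"class"` (majority vote) or `"votes"` (count matrix).
#' @param ... Unused.
#' @export
predict.sirna_forest <- function(object, X, type = c("class", "votes"), ...) {
  type <- match.arg(type)
  X <- unclass(X)
  attr(X, "labels") <- NULL
  attr(X, "levels") <- NULL
  storage.mode(X) <- "double"
  if (ncol(X) != object$p) stop("X has wrong number of columns")
  votes <- cpp_forest_votes(object$trees, X)
  colnames(votes) <- c("negative", "positive")
  if (type == "votes") return(votes)
  factor(ifelse(votes[, "positive"] > votes[, "negative"],
                "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Out-of-bag predictions and error of a fitted forest
#'
#' Each instance is voted on only by the trees in whose bootstrap it does
#' not appear — the forest's internal generalization estimate.
#'
#' @param forest A `sirna_forest`.
#' @param X The training feature matrix.
#' @return List with `pred` (factor; `NA` where an instance was in-bag for
#'   every tree) and `error` (misclassification rate over voted rows).
#' @export
oob_predictions <- function(forest, X) {
  X <- unclass(X); attr(X, "labels") <- NULL; attr(X, "levels") <- NULL
  storage.mode(X) <- "double"
  votes <- cpp_oob_votes(forest$trees, forest$inbag, X)
  tot <- rowSums(votes)
  pred <- ifelse(tot == 0L, NA_character_,
                 ifelse(votes[, 2L] > votes[, 1L], "positive", "negative"))
  pred <- factor(pred, levels = c("negative", "positive"))
  ok <- !is.na(pred)
  list(pred = pred,
       error = mean(pred[ok] != forest$y[ok]))
}

#' Out-of-bag permutation importance
#'
#' For each tree `t` and feature `j`, the raw per-tree score is the number
#' of tree-`t` oob instances classified correctly minus the number
#' classified correctly after permuting column `j` within that tree's oob
#' rows only. The feature's raw score is the mean over trees, its standard
#' error is `sd(per-tree scores)/sqrt(B)`, and the z-score is raw/se
#' (defined 0 when the standard error is 0). A normal-approximation
#' p-value for z is reported informationally.
#'
#' @param forest A fitted `sirna_forest`.
#' @param X The training feature matrix.
#' @param y The training labels (defaults to those stored in the forest).
#' @param seed Seed for the permutation streams; defaults to the forest
#'   seed + 1 so importance draws are distinct from bootstrap draws.
#' @return A `feature_importance` data frame: `feature`, `raw_score`,
#'   `se`, `z_score`, `p_value`, in training-column (schema) order, with
#'   attribute `n_empty_oob` flagging trees whose oob set was empty.
#' @export
oob_permutation_importance <- function(forest, X, y = NULL, seed = NULL) {
  stopifnot(inherits(forest, "sirna_forest"))
  d <- forest_xy(X, y %||% forest$y)
  if (nrow(d$X) != forest$n || ncol(d$X) != forest$p) {
    stop("X does not match the data the forest was fitted on")
  }
  B <- forest$config$n_trees
  perm_seeds <- derive_seeds(seed %||% (forest$config$seed + 1L), B)
  imp <- cpp_oob_importance(forest$trees, forest$inbag, d$X, d$y01,
                            perm_seeds)
  raw_t <- imp$raw                      # B x p per-tree count differences
  raw <- colMeans(raw_t)
  se <- apply(raw_t, 2L, stats::sd) / sqrt(B)
  z <- ifelse(se > 0, raw / se, 0)
  out <- data.frame(
    feature = forest$feature_names %||% paste0("V", seq_len(forest$p)),
    raw_score = raw, se = se, z_score = z,
    p_value = stats::pnorm(z, lower.tail = FALSE),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_empty_oob") <- sum(imp$empty_oob)
  class(out) <- c("feature_importance", "data.frame")
  out
}

#' Top-k features by importance z-score
#'
#' Ties at the boundary are broken by schema order: the feature appearing
#' earlier in the importance table wins.
#'
#' @param importance A `feature_importance` table.
#' @param k Number of features to keep (default 20).
#' @return Character vector of `k` feature names.
#' @export
top_k_by_z <- function(importance, k = 20L) {
  k <- as.integer(k)
  if (k > nrow(importance)) stop("k exceeds the number of features")
  ord <- order(-importance$z_score, seq_len(nrow(importance)))
  importance$feature[ord[seq_len(k)]]
}

#' Consensus feature selection across a grid of forests
#'
#' The full selection protocol: one forest of `B` trees per value of `m`
#' (default grid 2, 3, 5, 7, 9, 11, 13, 15, 17, 20 — ten forests), each
#' ranking features by importance z-score; the top `k` (default 20) of
#' each forest are recorded, and features ranked top-k by at least
#' `min_count` (default 5) of the forests are selected. The report lists,
#' per feature, how many forests selected it and the mean raw score and
#' mean z-score over those forests; when knockdown levels are supplied the
#' Pearson correlation of each selected feature with the inhibition level
#' (1 - remaining mRNA level) is appended.
#'
#' @param X Feature matrix or `feature_table`.
#' @param y Labels; taken from the table attribute when omitted.
#' @param m_values Integer grid for `m`.
#' @param B Trees per forest (default 1000).
#' @param k Rank cutoff per forest (default 20).
#' @param min_count Minimum number of forests that must rank a feature
#'   top-k (default 5).
#' @param seed Master seed; per-forest fitting and permutation seeds are
#'   derived from it, so the ten forests are independent but reproducible.
#' @param levels Optional remaining-mRNA levels for the correlation column.
#' @return A `consensus_selection`: list with `selected` (feature names in
#'   schema order), `counts` (named integer vector over all features),
#'   `per_forest_topk`, `report` (data frame sorted by mean z-score),
#'   and the protocol parameters.
#' @export
consensus_select <- function(X, y = NULL,
                             m_values = c(2L, 3L, 5L, 7L, 9L, 11L, 13L,
                                          15L, 17L, 20L),
                             B = 1000L, k = 20L, min_count = 5L, seed = 1L,
                             levels = NULL) {
  if (length(m_values) == 0L) stop("m_values must be non-empty")
  if (min_count > length(m_values)) {
    stop("min_count cannot exceed the number of forests")
  }
  d <- forest_xy(X, y)
  if (is.null(levels) && inherits(X, "feature_table")) {
    levels <- attr(X, "levels")
  }
  feat <- colnames(d$X) %||% paste0("V", seq_len(ncol(d$X)))
  nf <- length(m_values)
  seeds <- matrix(derive_seeds(seed, 2L * nf), nrow = 2L)

  per_forest_topk <- vector("list", nf)
  importances <- vector("list", nf)
  for (i in seq_len(nf)) {
    cfg <- forest_config(n_trees = B, m = m_values[i], seed = seeds[1L, i])
    forest <- fit_forest(d$X, d$y, config = cfg)
    imp <- oob_permutation_importance(forest, d$X, d$y, seed = seeds[2L, i])
    importances[[i]] <- imp
    per_forest_topk[[i]] <- top_k_by_z(imp, k = k)
  }
  names(per_forest_topk) <- paste0("m", m_values)

  counts <- stats::setNames(integer(length(feat)), feat)
  for (tk in per_forest_topk) counts[tk] <- counts[tk] + 1L
  selected <- feat[counts[feat] >= min_count]

  # Table-2-style report over the selected features: averages are taken
  # over the forests in which each feature ranked top-k.
  report <- do.call(rbind, lapply(selected, function(f) {
    sel_in <- vapply(per_forest_topk, function(tk) f %in% tk, logical(1L))
    raws <- vapply(importances[sel_in],
                   function(im) im$raw_score[im$feature == f], numeric(1L))
    zs <- vapply(importances[sel_in],
                 function(im) im$z_score[im$feature == f], numeric(1L))
    data.frame(feature = f, n_forests = sum(sel_in),
               mean_raw_score = mean(raws), mean_z_score = mean(zs),
               stringsAsFactors = FALSE)
  }))
  if (is.null(report)) {
    report <- data.frame(feature = character(), n_forests = integer(),
                         mean_raw_score = numeric(),
                         mean_z_score = numeric())
  } else {
    if (!is.null(levels)) {
      inhibition <- 1 - levels
      report$correlation <- vapply(report$feature, function(f) {
        stats::cor(d$X[, f], inhibition)
      }, numeric(1L))
    }
    report <- report[order(-report$mean_z_score), , drop = FALSE]
    rownames(report) <- NULL
  }

  structure(list(selected = selected, counts = counts,
                 per_forest_topk = per_forest_topk, report = report,
                 m_values = as.integer(m_values), B = as.integer(B),
                 k = as.integer(k), min_count = as.integer(min_count),
                 seed = as.integer(seed)),
            class = "consensus_selection")
}

#' @export
print.consensus_selection <- function(x, ...) {
  cat(sprintf(
    "consensus selection: %d forests (B = %d, top-%d, >= %d votes)\n",
    length(x$m_values), x$B, x$k, x$min_count))
  cat(sprintf("%d features selected\n", length(x$selected)))
  print(x$report)
  invisible(x)
}

#' Write a consensus-selection importance report as TSV
#'
#' @param selection A `consensus_selection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_importance_report <- function(selection, path) {
  stopifnot(inherits(selection, "consensus_selection"))
  utils::write.table(selection$report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
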