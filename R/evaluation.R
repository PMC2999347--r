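#' Confusion counts
#'
#' Cross-tabulates predicted against true labels into the four cells of
#' the binary confusion matrix.
#'
#' @param pred,truth Label vectors of equal length
#'   (`positive`/`negative`, logical or 0/1).
#' @return A `confusion_counts` list: `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(pred, truth) {
  pred <- as_label_factor(pred)
  truth <- as_label_factor(truth)
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  if (length(pred) < 1L) stop("need at least one instance")
  structure(list(
    TP = sum(pred == "positive" & truth == "positive"),
    TN = sum(pred == "negative" & truth == "negative"),
    FP = sum(pred == "positive" & truth == "negative"),
    FN = sum(pred == "negative" & truth == "positive")),
    class = "confusion_counts")
}

#' Confusion-matrix performance metrics
#'
#' Overall accuracy `(TP+TN)/N`, sensitivity `TP/(TP+FN)` and specificity
#' `TN/(TN+FP)` — reported as percentages — and the Matthews correlation
#' coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` in `[-1, 1]`.
#' A metric whose denominator is zero is reported as 0 and named in the
#' `degenerate` attribute rather than failing, so degenerate folds surface
#' in reports.
#'
#' @param counts A `confusion_counts`.
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`
#'   (percent) and `mcc`, with attribute `degenerate`.
#' @examples
#' classification_metrics(confusion(rep(c(1, 0), c(6, 4)),
#'                                  rep(c(1, 0), c(6, 4))))
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  if (total == 0L) stop("empty confusion table")
  degenerate <- character()
  ratio <- function(num, den, what) {
    if (den == 0) {
      degenerate <<- c(degenerate, what)
      return(0)
    }
    num / den
  }
  acc <- 100 * (TP + TN) / total
  sens <- 100 * ratio(TP, TP + FN, "sensitivity")
  spec <- 100 * ratio(TN, TN + FP, "specificity")
  mcc_den <- sqrt(as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  mcc <- ratio((as.numeric(TP) * TN - as.numeric(FP) * FN), mcc_den, "mcc")
  out <- c(accuracy = acc, sensitivity = sens, specificity = spec,
           mcc = mcc)
  attr(out, "degenerate") <- degenerate
  out
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the classification threshold over every distinct score value
#' (plus the two trivial endpoints), recording the false-positive and
#' true-positive rate at each threshold; tied scores move together, so the
#' trapezoidal area under the resulting curve equals the rank-based
#' (Mann-Whitney, tie-corrected) AUC exactly.
#'
#' @param scores Numeric classifier outputs (higher = more positive).
#' @param truth True labels; both classes must be present.
#' @return A `roc_curve`: list with `points` (data frame `threshold`,
#'   `fpr`, `tpr` from (0,0) to (1,1)) and `auc`.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as_label_factor(truth)
  if (length(scores) != length(truth)) {
    stop("scores and truth lengths differ")
  }
  n1 <- sum(truth == "positive")
  n0 <- sum(truth == "negative")
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- truth[ord] == "positive"
  # group tied scores: cumulative counts at each distinct threshold
  last_of_group <- c(diff(s) != 0, TRUE)
  tp <- cumsum(pos)[last_of_group]
  fp <- cumsum(!pos)[last_of_group]
  points <- data.frame(
    threshold = c(Inf, s[last_of_group], -Inf),
    fpr = c(0, fp / n0, 1),
    tpr = c(0, tp / n1, 1))
  points <- points[!duplicated(points[, c("fpr", "tpr")]), ]
  auc <- sum(diff(points$fpr) *
               (utils::head(points$tpr, -1) + utils::tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc), class = "roc_curve")
}

# Rank-based (Mann-Whitney) AUC with midrank tie correction; used as the
# cross-check that the threshold sweep is exact.
auc_rank <- function(scores, truth) {
  truth <- as_label_factor(truth)
  n1 <- sum(truth == "positive")
  n0 <- sum(truth == "negative")
  r <- rank(scores)
  (sum(r[truth == "positive"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "False positive rate",
                 ylab = "True positive rate", ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  graphics::legend("bottomright", sprintf("AUC = %.4f", x$auc), bty = "n")
}

#' Correlation of classifier output with knockdown efficacy
#'
#' Pearson correlation between continuous classifier scores and the
#' inhibition level `1 - remaining mRNA level`, so a positive coefficient
#' means higher output goes with stronger knockdown.
#'
#' @param scores Numeric classifier outputs.
#' @param levels Remaining relative mRNA levels in `[0, 1]`.
#' @return Pearson correlation coefficient.
#' @export
score_efficacy_correlation <- function(scores, levels) {
  if (length(scores) != length(levels)) stop("lengths differ")
  if (length(scores) < 3L) stop("need at least 3 observations")
  if (any(levels < 0 | levels > 1)) stop("levels must lie in [0, 1]")
  if (stats::sd(scores) == 0 || stats::sd(levels) == 0) {
    stop("zero variance in scores or levels")
  }
  stats::cor(scores, 1 - levels)
}

# Stratified (or plain) fold assignment; within-class sizes differ by <= 1.
assign_folds <- function(y, n_folds, seed, stratify = TRUE) {
  n <- length(y)
  fold <- integer(n)
  with_seed(seed, {
    if (stratify) {
      for (cl in levels(y)) {
        idx <- which(y == cl)
        if (length(idx) < n_folds) {
          stop("class '", cl, "' has fewer members (", length(idx),
               ") than folds (", n_folds, ")")
        }
        fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
    } else {
      if (n < n_folds) stop("fewer instances than folds")
      fold <- sample(rep_len(seq_len(n_folds), n))
    }
  })
  fold
}

#' Cross-validated evaluation of the SVM classifier
#'
#' Randomly distributes positive and negative instances into `n_folds`
#' folds (stratified per class by default, so every training split
#' contains both classes; `stratify = FALSE` restores plain
#' randomization). Each fold is held out once while the SVM is trained on
#' the rest; the held-out decision values from all folds are pooled, and
#' all reported measures — confusion counts, accuracy/sensitivity/
#' specificity/MCC, ROC/AUC, and (when knockdown levels are available) the
#' score-efficacy correlation — are computed once on the pooled
#' predictions.
#'
#' @param table A `feature_table` (labels and levels travel as
#'   attributes), or a plain matrix with `y` supplied.
#' @param y Optional labels when `table` is a plain matrix.
#' @param config An [svm_config()].
#' @param n_folds Number of folds (default 5).
#' @param seed Fold-assignment seed.
#' @param stratify Stratify fold assignment by class (default `TRUE`).
#' @param levels Optional remaining-mRNA levels (taken from the table
#'   attribute when omitted).
#' @return An `evaluation_report`: list with `counts`, `metrics`, `roc`,
#'   `auc`, `score_efficacy_r` (or `NA`), `fold_assignment`, and a
#'   `predictions` data frame (`id`, `fold`, `score`, `pred`, `truth`,
#'   `level`).
#' @export
cross_validate <- function(table, y = NULL, config = svm_config(),
                           n_folds = 5L, seed = 1L, stratify = TRUE,
                           levels = NULL) {
  if (inherits(table, "feature_table")) {
    if (is.null(y)) y <- attr(table, "labels")
    if (is.null(levels)) levels <- attr(table, "levels")
  }
  if (is.null(y)) stop("labels are required")
  y <- as_label_factor(y)
  X <- svm_design(table, NULL)
  n <- nrow(X)
  n_folds <- as.integer(n_folds)
  fold <- assign_folds(y, n_folds, seed, stratify)

  score <- numeric(n)
  for (f in seq_len(n_folds)) {
    test <- fold == f
    model <- train_svm(X[!test, , drop = FALSE], y[!test],
                       config = config)
    score[test] <- decision_values(model, X[test, , drop = FALSE])
  }

  pred <- factor(ifelse(score > 0, "positive", "negative"),
                 levels = c("negative", "positive"))
  counts <- confusion(pred, y)
  metrics <- classification_metrics(counts)
  roc <- roc_curve(score, y)
  r <- if (!is.null(levels) && stats::sd(score) > 0 &&
           stats::sd(levels) > 0) {
    score_efficacy_correlation(score, levels)
  } else {
    NA_real_
  }
  structure(list(
    counts = counts, metrics = metrics, roc = roc, auc = roc$auc,
    score_efficacy_r = r, fold_assignment = fold,
    predictions = data.frame(
      id = rownames(X) %||% as.character(seq_len(n)),
      fold = fold, score = score, pred = pred, truth = y,
      level = if (is.null(levels)) NA_real_ else levels,
      stringsAsFactors = FALSE),
    svm_config = config, n_folds = n_folds, seed = seed),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "%d-fold CV (pooled): accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%\n",
    x$n_folds, m[["accuracy"]], m[["sensitivity"]], m[["specificity"]]))
  cat(sprintf("MCC %.4f, AUC %.4f", m[["mcc"]], x$auc))
  if (!is.na(x$score_efficacy_r)) {
    cat(sprintf(", score-efficacy r %.4f", x$score_efficacy_r))
  }
  cat("\n")
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' One row per classifier in the conventional layout: Classifier,
#' Accuracy (%), Sensitivity (%), Specificity (%), MCC, AUC. ROC points
#' can be written alongside.
#'
#' @param report An `evaluation_report` (or named list of them).
#' @param path Output path.
#' @param roc_path Optional path for the pooled ROC points.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path, roc_path = NULL) {
  reports <- if (inherits(report, "evaluation_report")) {
    list(classifier = report)
  } else {
    report
  }
  rows <- do.call(rbind, lapply(names(reports), function(nm) {
    m <- reports[[nm]]$metrics
    data.frame(Classifier = nm,
               `Accuracy (%)` = round(m[["accuracy"]], 2),
               `Sensitivity (%)` = round(m[["sensitivity"]], 2),
               `Specificity (%)` = round(m[["specificity"]], 2),
               MCC = round(m[["mcc"]], 4),
               AUC = round(reports[[nm]]$auc, 4),
               check.names = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(roc_path)) {
    utils::write.table(reports[[1L]]$roc$points, roc_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
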