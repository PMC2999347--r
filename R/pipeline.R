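#' Run the full potency-prediction protocol
#'
#' Wires the pipeline end to end on one dataset: feature extraction,
#' consensus feature selection across the forest grid, SVM training on the
#' retained features, and stratified fivefold cross-validation with pooled
#' metrics. Three feature modes mirror the usual classifier comparison:
#' \describe{
#'   \item{`"selected"`}{consensus-selected features (the headline
#'     configuration);}
#'   \item{`"all"`}{all 120 features, selection skipped;}
#'   \item{`"positional"`}{only the 19 positional nucleotide codes.}
#' }
#' By default selection is performed once on the full dataset before
#' cross-validation, matching the reference protocol; note this lets the
#' selection see the evaluation folds, which biases CV metrics upward
#' ("optimistic" protocol). `nested = TRUE` instead redoes the selection
#' inside every training split, giving leak-free estimates at roughly
#' `n_folds` times the cost.
#'
#' @param dataset A `sirna_dataset` (or a path readable by
#'   [read_dataset()]).
#' @param seed Master seed driving selection, fold assignment, and any
#'   nested selection.
#' @param features_mode `"selected"`, `"all"` or `"positional"`.
#' @param m_values,B,k,min_count Consensus-selection protocol parameters
#'   (see [consensus_select()]).
#' @param gamma,C SVM parameters (defaults 1.2 / 1.2).
#' @param n_folds Cross-validation folds (default 5).
#' @param backend Folding backend for the free-energy feature.
#' @param nested Redo feature selection within each training fold.
#' @param outdir Optional directory; when given, writes `features.tsv`,
#'   `importance.tsv`, `selected.txt`, `model.json`, `evaluation.tsv`,
#'   `roc.tsv` and a `manifest.json` capturing configuration, seed and
#'   package version.
#' @return List with `features` (the `feature_table`), `selection`
#'   (`consensus_selection` or `NULL`), `model` (`sirna_svm` trained on
#'   the full dataset), `evaluation` (`evaluation_report`), and
#'   `manifest`.
#' @export
run_all <- function(dataset, seed = 1L,
                    features_mode = c("selected", "all", "positional"),
                    m_values = c(2L, 3L, 5L, 7L, 9L, 11L, 13L, 15L, 17L,
                                 20L),
                    B = 1000L, k = 20L, min_count = 5L,
                    gamma = 1.2, C = 1.2, n_folds = 5L,
                    backend = nussinov_backend(), nested = FALSE,
                    outdir = NULL) {
  features_mode <- match.arg(features_mode)
  if (is.character(dataset)) dataset <- read_dataset(dataset)
  stopifnot(inherits(dataset, "sirna_dataset"))
  if (anyNA(dataset$label)) stop("run_all needs a labeled dataset")

  seeds <- derive_seeds(seed, 2L + n_folds)
  tab <- extract_table(dataset, backend = backend)
  schema <- feature_schema()

  selection <- NULL
  subset <- switch(features_mode,
    all = NULL,
    positional = schema$names[schema$groups$positional],
    selected = {
      selection <- consensus_select(tab, m_values = m_values, B = B,
                                    k = k, min_count = min_count,
                                    seed = seeds[1L])
      if (length(selection$selected) == 0L) {
        stop("stage select: consensus selection returned no features")
      }
      selection$selected
    })
  cfg <- svm_config(gamma = gamma, C = C, feature_subset = subset)

  evaluation <- if (nested && features_mode == "selected") {
    nested_cv(tab, m_values = m_values, B = B, k = k,
              min_count = min_count, gamma = gamma, C = C,
              n_folds = n_folds, seed = seeds[2L],
              selection_seeds = seeds[-(1:2)])
  } else {
    cross_validate(tab, config = cfg, n_folds = n_folds, seed = seeds[2L])
  }
  model <- train_svm(tab, config = cfg)

  manifest <- list(
    package = "sirnaforest",
    version = as.character(utils::packageVersion("sirnaforest")),
    seed = seed, features_mode = features_mode, nested = nested,
    n = nrow(dataset), m_values = m_values, B = B, k = k,
    min_count = min_count, gamma = gamma, C = C, n_folds = n_folds,
    backend = backend$name,
    n_selected = if (is.null(subset)) ncol(tab) else length(subset))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(outdir, f)
    write_feature_table(tab, p("features.tsv"))
    if (!is.null(selection)) {
      write_importance_report(selection, p("importance.tsv"))
      writeLines(selection$selected, p("selected.txt"))
    }
    write_svm_model(model, p("model.json"))
    write_evaluation_report(evaluation, p("evaluation.tsv"),
                            roc_path = p("roc.tsv"))
    jsonlite::write_json(manifest, p("manifest.json"), digits = NA,
                         auto_unbox = TRUE)
  }

  list(features = tab, selection = selection, model = model,
       evaluation = evaluation, manifest = manifest)
}

# Leak-free variant: consensus selection is refitted on each training
# split; pooled holdout decision values are evaluated exactly as in
# cross_validate().
nested_cv <- function(tab, m_values, B, k, min_count, gamma, C, n_folds,
                      seed, selection_seeds) {
  y <- attr(tab, "labels")
  lv <- attr(tab, "levels")
  X <- svm_design(tab, NULL)
  fold <- assign_folds(as_label_factor(y), n_folds, seed)
  score <- numeric(nrow(X))
  for (f in seq_len(n_folds)) {
    test <- fold == f
    sel <- consensus_select(X[!test, , drop = FALSE], y[!test],
                            m_values = m_values, B = B, k = k,
                            min_count = min_count,
                            seed = selection_seeds[f])
    cfg <- svm_config(gamma = gamma, C = C,
                      feature_subset = sel$selected)
    model <- train_svm(X[!test, , drop = FALSE], y[!test], config = cfg)
    score[test] <- decision_values(model, X[test, , drop = FALSE])
  }
  y <- as_label_factor(y)
  pred <- factor(ifelse(score > 0, "positive", "negative"),
                 levels = c("negative", "positive"))
  counts <- confusion(pred, y)
  roc <- roc_curve(score, y)
  r <- if (!is.null(lv)) score_efficacy_correlation(score, lv) else NA_real_
  structure(list(
    counts = counts, metrics = classification_metrics(counts), roc = roc,
    auc = roc$auc, score_efficacy_r = r, fold_assignment = fold,
    predictions = data.frame(id = rownames(X), fold = fold, score = score,
                             pred = pred, truth = y,
                             level = if (is.null(lv)) NA_real_ else lv,
                             stringsAsFactors = FALSE),
    svm_config = svm_config(gamma = gamma, C = C), n_folds = n_folds,
    seed = seed), class = "evaluation_report")
}
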