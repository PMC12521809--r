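#' Random-forest hyperparameter grid
#'
#' The exhaustive grid swept for the classifiers: every combination of
#' forest size and maximum tree depth is evaluated by 5-fold
#' cross-validated accuracy with a fixed fold assignment.
#'
#' @param n_trees forest sizes (default 20, 50, 100, 200, 500, 1000, 2000).
#' @param max_depths maximum tree depths (default 2..7).
#' @param folds number of CV folds (>= 2; default 5).
#' @param seed integer seed controlling fold assignment and tree growing.
#' @return list of class `rf_grid`.
#' @export
rf_grid <- function(n_trees = c(20, 50, 100, 200, 500, 1000, 2000),
                    max_depths = 2:7, folds = 5, seed = 1L) {
  if (any(n_trees < 1) || any(max_depths < 1) || folds < 2)
    stop("grid entries must be positive and folds >= 2")
  structure(list(n_trees = sort(unique(n_trees)),
                 max_depths = sort(unique(max_depths)),
                 folds = folds, seed = as.integer(seed)),
            class = "rf_grid")
}

.check_class_sizes <- function(y, folds) {
  tab <- table(y)
  bad <- names(tab)[tab < folds]
  if (length(bad))
    stop(sprintf("class '%s' has fewer members (%d) than folds (%d)",
                 bad[1], tab[bad[1]], folds))
}

#' Exhaustive grid search for a random-forest classifier
#'
#' Evaluates every (n_trees, max_depth) combination by mean accuracy over
#' stratified k-fold cross-validation, with the fold assignment held fixed
#' across grid cells so cells are compared on identical splits. Ties are
#' broken toward fewer trees, then shallower depth (parsimony).
#'
#' @param X numeric matrix (samples x features), typically M values on a
#'   selected `FeatureSet`.
#' @param y class labels (factor or character).
#' @param grid an [rf_grid()].
#' @param stratify stratify the CV folds by class (recommended with
#'   imbalanced classes; switchable for sensitivity analyses).
#' @return list with `n_trees`, `max_depth`, and `cv` — a data.frame of
#'   mean CV accuracy per grid cell (one row per configuration).
#' @export
grid_search_rf <- function(X, y, grid = rf_grid(), stratify = TRUE) {
  stopifnot(inherits(grid, "rf_grid"))
  y <- factor(y)
  .check_class_sizes(y, grid$folds)
  fold <- make_folds(length(y), grid$folds, seed = grid$seed,
                     strata = if (stratify) y else NULL)
  cells <- expand.grid(n_trees = grid$n_trees, max_depth = grid$max_depths,
                       KEEP.OUT.ATTRS = FALSE)
  cells$accuracy <- NA_real_
  for (i in seq_len(nrow(cells))) {
    acc <- numeric(grid$folds)
    for (f in seq_len(grid$folds)) {
      tr <- fold != f
      fit <- .fit_rf(X[tr, , drop = FALSE], y[tr],
                     n_trees = cells$n_trees[i],
                     max_depth = cells$max_depth[i],
                     seed = grid$seed + f)
      pred <- .predict_rf(fit, X[!tr, , drop = FALSE])
      acc[f] <- mean(pred == y[!tr])
    }
    cells$accuracy[i] <- mean(acc)
  }
  # parsimony tie-break: scan cells in (n_trees, depth) order, keep first
  # strict improvement
  ord <- order(cells$n_trees, cells$max_depth)
  cells <- cells[ord, ]
  best <- which.max(cells$accuracy)
  list(n_trees = cells$n_trees[best], max_depth = cells$max_depth[best],
       cv = cells)
}

.fit_rf <- function(X, y, n_trees, max_depth, seed) {
  df <- data.frame(.y = y, X, check.names = FALSE)
  ranger::ranger(dependent.variable.name = ".y", data = df,
                 num.trees = n_trees, max.depth = max_depth,
                 importance = "impurity", seed = seed, num.threads = 1L,
                 verbose = FALSE)
}

.predict_rf <- function(fit, X) {
  stats::predict(fit, data = data.frame(X, check.names = FALSE),
                 num.threads = 1L)$predictions
}

#' Cross-validated random-forest classifier with out-of-fold predictions
#'
#' Trains one forest per fold at fixed hyperparameters, predicts each
#' held-out fold (so every sample gets exactly one out-of-fold
#' prediction), then refits a final forest on all data. Out-of-fold
#' confusion statistics estimate generalization; the final model carries
#' the impurity-based feature importances.
#'
#' @param X numeric matrix (samples x features).
#' @param y class labels.
#' @param n_trees,max_depth forest hyperparameters.
#' @param folds number of CV folds.
#' @param seed integer seed (folds and trees).
#' @param positive positive class for binary confusion statistics.
#' @param stratify stratify the CV folds by class.
#' @return A `FitResult` list: `model` (final ranger fit), `features`,
#'   `oof` (out-of-fold labels), `y`, `fold`, `metrics`
#'   (`ConfusionStats` on the OOF predictions), `provenance`.
#' @export
train_rf_cv <- function(X, y, n_trees = 500, max_depth = 5, folds = 5,
                        seed = 1L, positive = NULL, stratify = TRUE) {
  y <- factor(y)
  .check_class_sizes(y, folds)
  fold <- make_folds(length(y), folds, seed = seed,
                     strata = if (stratify) y else NULL)
  oof <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- .fit_rf(X[tr, , drop = FALSE], y[tr], n_trees, max_depth,
                   seed = seed + f)
    oof[!tr] <- .predict_rf(fit, X[!tr, , drop = FALSE])
  }
  final <- .fit_rf(X, y, n_trees, max_depth, seed = seed)
  structure(list(model = final, features = colnames(X), oof = oof, y = y,
                 fold = fold,
                 metrics = confusion_stats(y, oof, levels(y),
                                           positive = positive),
                 provenance = list(type = "random_forest",
                                   n_trees = n_trees, max_depth = max_depth,
                                   folds = folds, seed = seed,
                                   mtry = "ranger default (sqrt(p))",
                                   bootstrap = "with replacement",
                                   stratified_folds = stratify)),
            class = "FitResult")
}

#' Confusion matrix and agreement statistics
#'
#' Builds the class-by-class confusion matrix (rows = truth) and computes
#' overall accuracy, Cohen's kappa (chance agreement from the row/column
#' marginals), and one-vs-rest sensitivity, specificity, and balanced
#' accuracy per class. For binary problems a declared positive class
#' singles out the headline sensitivity/specificity.
#'
#' @param y_true,y_pred equal-length label vectors; every label must be in
#'   `class_order`.
#' @param class_order class labels in display order.
#' @param positive optional positive class.
#' @return A `ConfusionStats` list: `table`, `accuracy`, `kappa`,
#'   `by_class` (data.frame with sensitivity, specificity,
#'   balanced_accuracy), plus `sensitivity`/`specificity` for the
#'   positive class when declared.
#' @examples
#' confusion_stats(c("a", "a", "b"), c("a", "b", "b"), c("a", "b"))$accuracy
#' @export
confusion_stats <- function(y_true, y_pred,
                            class_order = sort(unique(c(y_true, y_pred))),
                            positive = NULL) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- factor(as.character(y_true), levels = class_order)
  y_pred <- factor(as.character(y_pred), levels = class_order)
  if (anyNA(y_true) || anyNA(y_pred))
    stop("labels outside `class_order`")
  tab <- table(truth = y_true, predicted = y_pred)
  n <- sum(tab)
  acc <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (abs(1 - pe) < 1e-12) 0 else (acc - pe) / (1 - pe)
  by_class <- do.call(rbind, lapply(class_order, function(cl) {
    tp <- tab[cl, cl]
    fn <- sum(tab[cl, ]) - tp
    fp <- sum(tab[, cl]) - tp
    tn <- n - tp - fn - fp
    sens <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
    data.frame(class = cl, sensitivity = sens, specificity = spec,
               balanced_accuracy = (sens + spec) / 2,
               stringsAsFactors = FALSE)
  }))
  out <- list(table = tab, accuracy = acc, kappa = kappa,
              by_class = by_class)
  if (!is.null(positive)) {
    if (!positive %in% class_order) stop("`positive` not in class_order")
    i <- match(positive, by_class$class)
    out$positive <- positive
    out$sensitivity <- by_class$sensitivity[i]
    out$specificity <- by_class$specificity[i]
  }
  class(out) <- "ConfusionStats"
  out
}

#' @export
print.ConfusionStats <- function(x, ...) {
  print(x$table)
  cat(sprintf("accuracy %.4f, kappa %.4f\n", x$accuracy, x$kappa))
  invisible(x)
}

#' Serialize a fit result to a directory
#'
#' Writes the feature list (one probe per line), out-of-fold predictions
#' (CSV: sample index, truth, prediction, fold), headline metrics (JSON),
#' and the model object (RDS).
#'
#' @param fit a `FitResult`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_fit_result <- function(fit, dir) {
  stopifnot(inherits(fit, "FitResult"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(as.character(fit$features), file.path(dir, "features.txt"))
  oof <- data.frame(index = seq_along(fit$oof),
                    actual = as.character(fit$y %||% NA),
                    predicted = as.character(fit$oof), fold = fit$fold)
  utils::write.csv(oof, file.path(dir, "oof_predictions.csv"),
                   row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    m <- fit$metrics
    flat <- if (inherits(m, "ConfusionStats"))
      list(accuracy = m$accuracy, kappa = m$kappa) else m
    jsonlite::write_json(flat, file.path(dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  saveRDS(fit$model, file.path(dir, "model.rds"))
  invisible(dir)
}
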