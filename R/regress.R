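#' Scale weekly alcohol categories to a 0-1 health score
#'
#' Maps the five weekly-consumption categories to an evenly spaced score
#' with 1 = healthiest (no alcohol) and 0 = least healthy (15+ drinks):
#' `"0"` -> 1, `"1-4"` -> 0.75, `"4-7"` -> 0.5, `"8-14"` -> 0.25,
#' `"15+"` -> 0. The endpoints are fixed by the scoring convention; even
#' spacing of the intermediate levels is a documented choice, overridable
#' via `weights`.
#'
#' @param categories character/factor vector of category labels.
#' @param weights optional named numeric vector overriding the mapping.
#' @return numeric vector in \[0, 1\].
#' @examples
#' scale_alcohol(c("0", "4-7", "15+"))  # 1.0 0.5 0.0
#' @export
scale_alcohol <- function(categories, weights = NULL) {
  if (is.null(weights))
    weights <- stats::setNames(c(1, 0.75, 0.5, 0.25, 0), alcohol_levels)
  categories <- as.character(categories)
  unknown <- setdiff(unique(categories), names(weights))
  if (length(unknown))
    stop(sprintf("unknown alcohol category: '%s'", unknown[1]))
  unname(weights[categories])
}

#' Cross-validated feed-forward regressor with out-of-fold predictions
#'
#' Trains one network per fold (feature standardization fitted on the
#' training fold only), predicts the held-out fold so every sample gets
#' exactly one out-of-fold prediction, then refits a final model on all
#' data. Used for the alcohol, BMI, and chronological-age regressors.
#'
#' @param X numeric matrix (samples x features), M values on a selected
#'   `FeatureSet`.
#' @param y numeric target (finite, non-constant).
#' @param arch an [arch_spec()].
#' @param cfg a [train_config()].
#' @return A `FitResult`: `model` (final `ffnn_model`), `features`, `oof`
#'   (numeric out-of-fold predictions), `y`, `fold`, `metrics`
#'   ([regression_metrics()] on the OOF predictions), `provenance`.
#' @export
train_ffnn_cv <- function(X, y, arch = arch_spec("h3"),
                          cfg = train_config()) {
  stopifnot(inherits(arch, "arch_spec"), inherits(cfg, "train_config"))
  if (!all(is.finite(X))) stop("X must be finite")
  if (!all(is.finite(y))) stop("y must be finite")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (stats::sd(y) == 0) stop("y is constant")
  fold <- make_folds(length(y), cfg$folds, seed = cfg$seed)
  oof <- rep(NA_real_, length(y))
  for (f in seq_len(cfg$folds)) {
    tr <- fold != f
    m <- .ffnn_fit_one(X[tr, , drop = FALSE], y[tr], arch$hidden_sizes,
                       cfg, seed = cfg$seed + f)
    oof[!tr] <- predict(m, X[!tr, , drop = FALSE])
  }
  final <- .ffnn_fit_one(X, y, arch$hidden_sizes, cfg, seed = cfg$seed)
  structure(list(model = final, features = colnames(X), oof = oof, y = y,
                 fold = fold, metrics = regression_metrics(oof, y),
                 provenance = list(type = "ffnn", preset = arch$preset,
                                   hidden_sizes = arch$hidden_sizes,
                                   lr = cfg$lr, epochs = cfg$epochs,
                                   standardize = cfg$standardize,
                                   reference_protocol =
                                     (cfg$lr == 1e-6 && cfg$epochs == 2500),
                                   folds = cfg$folds, seed = cfg$seed)),
            class = "FitResult")
}

#' Regression accuracy metrics
#'
#' Pearson correlation (with a two-sided p-value from the t transform),
#' mean absolute error, and root mean squared error between predicted and
#' actual values.
#'
#' @param pred,actual equal-length numeric vectors (length >= 3, neither
#'   constant).
#' @return list of class `RegressionMetrics` with `pearson_r`, `r_pvalue`,
#'   `mae`, `rmse`, `n`.
#' @examples
#' regression_metrics(c(1, 2, 3), c(1.5, 2.5, 3.5))
#' @export
regression_metrics <- function(pred, actual) {
  if (length(pred) != length(actual)) stop("length mismatch")
  if (length(pred) < 3) stop("need at least 3 pairs")
  if (stats::sd(pred) == 0 || stats::sd(actual) == 0)
    stop("correlation undefined for constant input")
  ct <- stats::cor.test(pred, actual)
  err <- pred - actual
  structure(list(pearson_r = unname(ct$estimate), r_pvalue = ct$p.value,
                 mae = mean(abs(err)), rmse = sqrt(mean(err^2)),
                 n = length(pred)),
            class = "RegressionMetrics")
}

#' @export
print.RegressionMetrics <- function(x, ...) {
  cat(sprintf("r = %.4f (p = %.3g), MAE = %.4f, RMSE = %.4f (n = %d)\n",
              x$pearson_r, x$r_pvalue, x$mae, x$rmse, x$n))
  invisible(x)
}

#' Delta age (age acceleration)
#'
#' Elementwise difference, epigenetic (predicted) age minus chronological
#' age. Positive values indicate accelerated epigenetic aging.
#'
#' @param pred_age,chron_age equal-length numeric vectors, years.
#' @return numeric vector of residuals (years).
#' @examples
#' delta_age(82.4, 91.2)  # -8.8
#' @export
delta_age <- function(pred_age, chron_age) {
  if (length(pred_age) != length(chron_age)) stop("length mismatch")
  pred_age - chron_age
}
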