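#' Principal-component scores of a methylation matrix
#'
#' PCA of the mean-centered (unscaled) sample x probe matrix; scores are
#' ordered by decreasing explained variance. Sign convention: within each
#' component, the loading of largest absolute value is made positive, so
#' scores are reproducible across platforms.
#'
#' @param mat a `MethylMatrix` (typically M space) or numeric matrix.
#' @param n_components components to keep; capped at
#'   `min(n_samples - 1, n_probes)`.
#' @return samples x components score matrix with attributes
#'   `var_explained` (per-component fraction of total variance) and
#'   `sdev`.
#' @export
pca_scores <- function(mat, n_components = 1000) {
  x <- unclass(mat)
  if (nrow(x) < 2) stop("need at least 2 samples")
  n_components <- min(n_components, nrow(x) - 1L, ncol(x))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) scores[, j] <- -scores[, j]
  }
  attr(scores, "var_explained") <- pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2)
  attr(scores, "sdev") <- pc$sdev[seq_len(k)]
  scores
}

#' Per-component batch silhouettes
#'
#' Screens for batch effects by treating each principal component as a
#' one-dimensional embedding and computing the mean silhouette width of
#' every batch under absolute-difference distance. A positive width means
#' samples of that batch sit closer to each other than to the nearest
#' other batch along that component — the signature of a batch effect;
#' silhouettes near or below zero indicate no batch clustering. Singleton
#' batches receive width 0 by convention.
#'
#' @param scores samples x components matrix from [pca_scores()].
#' @param batch_labels batch (plate) label per sample; >= 2 distinct
#'   batches required.
#' @param n_components number of leading components to analyze (capped at
#'   `ncol(scores)`).
#' @return A `SilhouetteReport` data.frame: `component`, `batch`, `width`;
#'   attribute `positive` holds the subset with `width > 0`.
#' @export
batch_silhouette <- function(scores, batch_labels, n_components = 1000) {
  batch <- factor(batch_labels)
  if (nlevels(batch) < 2) stop("need at least 2 distinct batches")
  if (length(batch) != nrow(scores))
    stop("batch labels must match score rows")
  k <- min(n_components, ncol(scores))
  cl <- as.integer(batch)
  rows <- vector("list", k)
  for (j in seq_len(k)) {
    sil <- cluster::silhouette(cl, dist(scores[, j]))
    avg <- tapply(sil[, "sil_width"], levels(batch)[sil[, "cluster"]], mean)
    rows[[j]] <- data.frame(component = j, batch = names(avg),
                            width = as.numeric(avg),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "positive") <- out[out$width > 0, , drop = FALSE]
  class(out) <- c("SilhouetteReport", "data.frame")
  out
}

# relevel every factor/character covariate so the largest class is the
# reference (stabilizes contrasts with imbalanced categories)
.relevel_largest <- function(df) {
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.character(v)) v <- factor(v)
    if (is.factor(v)) {
      ref <- names(sort(table(v), decreasing = TRUE))[1]
      df[[nm]] <- stats::relevel(v, ref = ref)
    }
  }
  df
}

#' Linear association model for a predicted outcome
#'
#' Ordinary least squares of an outcome (delta age, predicted smoking,
#' predicted BMI, or predicted alcohol) on lifestyle, health, demographic,
#' and technical covariates. Categorical covariates are expanded to
#' indicator contrasts against their largest class. Two-sided t-test
#' p-values are Benjamini-Hochberg adjusted across the model's
#' non-intercept coefficients.
#'
#' @param outcome numeric vector.
#' @param covariates data.frame of covariates (numeric and
#'   factor/character columns), one row per sample.
#' @param outcome_name label recorded in the result.
#' @return An `AssociationResult` data.frame: `term`, `estimate`, `se`,
#'   `t`, `p`, `fdr` (NA for the intercept); attribute `formula` records
#'   the fitted design.
#' @export
fit_association <- function(outcome, covariates, outcome_name = "outcome") {
  if (!is.data.frame(covariates)) stop("`covariates` must be a data.frame")
  if (length(outcome) != nrow(covariates))
    stop("outcome length must match covariate rows")
  covariates <- .relevel_largest(covariates)
  df <- data.frame(.outcome = outcome, covariates, check.names = TRUE)
  if (nrow(df) <= ncol(stats::model.matrix(.outcome ~ ., df)))
    stop("more coefficients than samples")
  fit <- stats::lm(.outcome ~ ., data = df)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("rank-deficient design; collinear columns: %s",
                 paste(bad, collapse = ", ")))
  }
  cf <- summary(fit)$coefficients
  out <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                    t = cf[, 3], p = cf[, 4], stringsAsFactors = FALSE)
  is_cov <- out$term != "(Intercept)"
  out$fdr <- NA_real_
  out$fdr[is_cov] <- stats::p.adjust(out$p[is_cov], method = "BH")
  rownames(out) <- NULL
  attr(out, "formula") <- sprintf("%s ~ %s", outcome_name,
                                  paste(names(covariates), collapse = " + "))
  class(out) <- c("AssociationResult", "data.frame")
  out
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test with the Welch-Satterthwaite degrees of
#' freedom. When both groups are constant with equal means the test is
#' degenerate and returns t = 0, p = 1 by convention.
#'
#' @param groupA,groupB numeric vectors, each of length >= 2, finite.
#' @return list with `t`, `df`, `p`.
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))
#' @export
welch_t <- function(groupA, groupB) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs >= 2 observations")
  if (!all(is.finite(groupA)) || !all(is.finite(groupB)))
    stop("inputs must be finite")
  m1 <- mean(groupA); m2 <- mean(groupB)
  v1 <- stats::var(groupA); v2 <- stats::var(groupB)
  n1 <- length(groupA); n2 <- length(groupB)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    if (m1 == m2) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    return(list(t = sign(m1 - m2) * Inf, df = n1 + n2 - 2, p = 0))
  }
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(t = tstat, df = df, p = p)
}
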