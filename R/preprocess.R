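#' Beta to M-value transform
#'
#' Computes `M = log2(beta / (1 - beta))` after clipping beta into
#' `[eps, 1 - eps]` to avoid infinities. M values are the working scale
#' for model training: they are variance-stabilized near the 0/1 extremes
#' where beta values compress small changes.
#'
#' @param mat a `MethylMatrix` in beta space.
#' @param eps clip bound, must lie in (0, 0.5); default `1e-5`, so
#'   beta = 0 maps to `log2(1e-5 / (1 - 1e-5))` (about -16.61).
#' @return a `MethylMatrix` in M space.
#' @examples
#' x <- matrix(c(0.5, 0.8), 1, 2, dimnames = list("s1", c("cg1", "cg2")))
#' beta_to_m(methyl_matrix(x, "beta"))  # 0 and 2
#' @export
beta_to_m <- function(mat, eps = 1e-5) {
  stopifnot(inherits(mat, "MethylMatrix"))
  if (methyl_space(mat) != "beta") stop("input must be in beta space")
  if (length(eps) != 1 || !is.finite(eps) || eps <= 0 || eps >= 0.5)
    stop("`eps` must lie in (0, 0.5)")
  b <- pmin(pmax(unclass(mat), eps), 1 - eps)
  methyl_matrix(log2(b / (1 - b)), "M")
}

#' M-value to beta transform
#'
#' Inverse of [beta_to_m()]: `beta = 2^M / (1 + 2^M)`. Round-trips
#' `beta_to_m` exactly (to numerical precision) away from the clip bounds.
#'
#' @param mat a `MethylMatrix` in M space.
#' @return a `MethylMatrix` in beta space.
#' @export
m_to_beta <- function(mat) {
  stopifnot(inherits(mat, "MethylMatrix"))
  if (methyl_space(mat) != "M") stop("input must be in M space")
  m <- unclass(mat)
  # stable logistic: never overflows for large |M|
  b <- ifelse(m > 0, 1 / (1 + 2^(-m)), 2^m / (1 + 2^m))
  methyl_matrix(b, "beta")
}

#' Reference-based cell-fraction estimation
#'
#' Estimates per-sample cell-type fractions by nonnegative least squares
#' against reference methylation profiles: for each sample, fractions `f`
#' minimize `||t(R) f - b||^2` subject to `f >= 0` over the probes shared
#' between the sample matrix and the reference, then are rescaled to sum
#' to at most 1. Used to produce the epithelial-fraction covariate of the
#' delta-age association model; fractions are never fed into predictor
#' training (they are themselves derived from the methylation).
#'
#' @param mat a `MethylMatrix` in beta space.
#' @param reference cell type x probe beta matrix (row names = cell types,
#'   column names = probe IDs, a subset of `mat`'s probes).
#' @return data.frame of fractions, one row per sample, one column per
#'   reference cell type.
#' @export
estimate_cell_fractions <- function(mat, reference) {
  stopifnot(inherits(mat, "MethylMatrix"))
  if (methyl_space(mat) != "beta") stop("input must be in beta space")
  if (!is.matrix(reference) || is.null(rownames(reference)) ||
      is.null(colnames(reference)))
    stop("`reference` must be a cell type x probe matrix with dimnames")
  if (nrow(reference) < 2) stop("need at least 2 reference cell types")
  shared <- intersect(colnames(reference), colnames(mat))
  if (length(shared) < 2 * nrow(reference))
    stop("fewer than 2 overlapping probes per cell type")
  A <- t(reference[, shared, drop = FALSE])   # probes x cell types
  X <- unclass(mat)[, shared, drop = FALSE]
  frac <- t(apply(X, 1L, function(b) {
    f <- pracma::lsqnonneg(A, as.numeric(b))$x
    s <- sum(f)
    if (s > 1) f <- f / s
    f
  }))
  colnames(frac) <- rownames(reference)
  as.data.frame(frac, row.names = rownames(mat))
}
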