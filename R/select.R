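#' Per-CpG Pearson correlation with a target
#'
#' Computes the Pearson correlation coefficient of every probe with a
#' numeric target across samples. Binary targets coded 0/1 yield the
#' point-biserial correlation (the same formula). Probes with zero
#' variance receive r = 0 so the vector remains totally ordered for
#' ranking.
#'
#' @param mat a `MethylMatrix` in M space.
#' @param target numeric vector, one value per sample; must not be
#'   constant.
#' @param target_name label recorded in the result.
#' @return A `CorrelationVector`: named numeric vector of r values (one
#'   per probe) with attributes `target_name` and `n_used`.
#' @export
cpg_correlations <- function(mat, target, target_name = "target") {
  stopifnot(inherits(mat, "MethylMatrix"))
  if (methyl_space(mat) != "M") stop("input must be in M space")
  x <- unclass(mat)
  if (length(target) != nrow(x))
    stop("`target` length must equal the number of samples")
  if (nrow(x) < 3) stop("need at least 3 samples")
  if (stats::sd(target) == 0) stop("`target` is constant")
  r <- suppressWarnings(as.numeric(stats::cor(target, x)))
  r[!is.finite(r)] <- 0   # zero-variance probes
  structure(stats::setNames(r, colnames(x)),
            target_name = target_name, n_used = nrow(x),
            class = "CorrelationVector")
}

#' Top-k feature selection by absolute correlation
#'
#' Returns the k probes with largest |r|, ordered by |r| descending with
#' ties broken lexicographically by probe ID (for cross-platform
#' reproducibility). Ranking by absolute value keeps both hyper- and
#' hypomethylated signal; downstream models are sign-agnostic.
#'
#' @param corr a `CorrelationVector` from [cpg_correlations()].
#' @param k number of probes to keep (positive, at most the number of
#'   probes).
#' @param absolute rank by |r| (default) or by signed r.
#' @return A `FeatureSet`: character vector of probe IDs with a
#'   `provenance` attribute (target, k, scheme).
#' @export
select_top_k <- function(corr, k, absolute = TRUE) {
  stopifnot(inherits(corr, "CorrelationVector"))
  if (length(k) != 1 || !is.finite(k) || k <= 0) stop("`k` must be positive")
  if (k > length(corr)) stop("`k` exceeds the number of probes")
  score <- if (absolute) abs(as.numeric(corr)) else as.numeric(corr)
  ord <- order(-score, names(corr))
  feature_set(names(corr)[ord[seq_len(k)]],
              provenance = list(target = attr(corr, "target_name"), k = k,
                                scheme = "topk"))
}

#' Union-of-top-k selection for a multi-class target
#'
#' For each named class, probes are correlated against the one-hot class
#' indicator and the top `k_per_class` by |r| are taken; the returned set
#' is the union across classes (de-duplicated in class order). Classes not
#' listed (e.g. a catch-all "Other" group) take no part in selection.
#'
#' @param mat a `MethylMatrix` in M space.
#' @param labels character/factor vector of class labels per sample.
#' @param k_per_class probes per class (default 2500).
#' @param classes classes to select for; each must appear at least twice.
#' @return A `FeatureSet` of size between `k_per_class` and
#'   `k_per_class * length(classes)`.
#' @export
select_union_per_class <- function(mat, labels, k_per_class = 2500,
                                   classes = setdiff(unique(labels), "Other")) {
  stopifnot(inherits(mat, "MethylMatrix"))
  labels <- as.character(labels)
  if (length(labels) != nrow(mat))
    stop("`labels` length must equal the number of samples")
  counts <- table(labels)
  for (cl in classes)
    if (is.na(counts[cl]) || counts[cl] < 2)
      stop(sprintf("class '%s' absent or present fewer than 2 times", cl))
  sel <- character(0)
  for (cl in classes) {
    corr <- cpg_correlations(mat, as.numeric(labels == cl),
                             target_name = cl)
    sel <- c(sel, select_top_k(corr, k_per_class))
  }
  feature_set(unique(sel),
              provenance = list(target = classes, k = k_per_class,
                                scheme = "union"))
}

#' Construct / serialize feature sets
#'
#' A `FeatureSet` is an ordered, duplicate-free character vector of probe
#' IDs carrying a provenance record (target(s), k, selection scheme). On
#' disk it is one probe per line with a `#`-prefixed provenance header.
#'
#' @param probes character vector of probe IDs, no duplicates.
#' @param provenance list with elements `target`, `k`, `scheme`.
#' @return a `FeatureSet`.
#' @export
feature_set <- function(probes, provenance = list()) {
  probes <- as.character(probes)
  if (anyDuplicated(probes)) stop("duplicate probes in feature set")
  structure(probes, provenance = provenance,
            class = c("FeatureSet", "character"))
}

#' @rdname feature_set
#' @param fs a `FeatureSet`.
#' @param path file path.
#' @export
write_feature_set <- function(fs, path) {
  stopifnot(inherits(fs, "FeatureSet"))
  pv <- attr(fs, "provenance")
  hdr <- sprintf("# target=%s k=%s scheme=%s",
                 paste(pv$target, collapse = ","),
                 pv$k %||% NA, pv$scheme %||% NA)
  writeLines(c(hdr, as.character(fs)), path)
  invisible(path)
}

#' @rdname feature_set
#' @export
read_feature_set <- function(path) {
  lines <- readLines(path)
  feature_set(lines[!startsWith(lines, "#") & nzchar(lines)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
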