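#' Importance vector container
#'
#' A named numeric vector (probe -> importance) with a method tag and a
#' description of the background the importances were computed against.
#' Impurity importances are nonnegative and normalized to sum 1; network
#' attributions are signed and ranked by absolute value.
#'
#' @param values named numeric vector.
#' @param method method tag (e.g. `"impurity"`, `"integrated_gradients"`).
#' @param background free-text background description.
#' @return an `ImportanceVector`.
#' @export
importance_vector <- function(values, method, background = "") {
  if (is.null(names(values))) stop("importances must be named by probe")
  if (!all(is.finite(values))) stop("importances must be finite")
  structure(values, method = method, background = background,
            class = "ImportanceVector")
}

#' Impurity-based feature importance of a random forest
#'
#' Mean decrease in Gini impurity accumulated over all trees, per feature,
#' normalized to sum 1. An optional replicate-ensemble standard deviation
#' is computed by refitting `sd_replicates` forests under different seeds
#' (requires the training data).
#'
#' @param fit a `FitResult` from [train_rf_cv()] (or a fitted ranger
#'   model).
#' @param X,y training data, only needed when `sd_replicates > 0`.
#' @param sd_replicates number of replicate forests for the importance sd
#'   (0 = skip).
#' @return an `ImportanceVector`; when replicates were run, an `sd`
#'   attribute holds the per-feature standard deviation across replicates.
#' @export
rf_importance <- function(fit, X = NULL, y = NULL, sd_replicates = 0) {
  model <- if (inherits(fit, "FitResult")) fit$model else fit
  if (!inherits(model, "ranger")) stop("not a fitted random forest")
  imp <- ranger::importance(model)
  if (is.null(imp) || !length(imp)) stop("model carries no importances")
  total <- sum(imp)
  if (total > 0) imp <- imp / total
  out <- importance_vector(imp, method = "impurity",
                           background = "mean decrease in impurity, normalized to sum 1")
  if (sd_replicates > 0) {
    if (is.null(X) || is.null(y))
      stop("X and y are required for replicate importance sd")
    prov <- if (inherits(fit, "FitResult")) fit$provenance else
      list(n_trees = model$num.trees, max_depth = 0, seed = 1L)
    reps <- vapply(seq_len(sd_replicates), function(r) {
      m <- .fit_rf(X, factor(y), prov$n_trees, prov$max_depth,
                   seed = prov$seed + 1000L + r)
      v <- ranger::importance(m)
      if (sum(v) > 0) v / sum(v) else v
    }, numeric(length(imp)))
    attr(out, "sd") <- apply(reps, 1L, stats::sd)
  }
  out
}

#' Path-integral (integrated-gradients) attribution for deep regressors
#'
#' Attributes each prediction to the input CpGs by integrated gradients
#' against the background-mean baseline: for sample `x`,
#' `a_i = (x_i - b_i) * mean_j grad_i f(b + alpha_j (x - b))` with
#' midpoint steps `alpha_j`. Attributions satisfy completeness — they sum
#' to `f(x) - f(b)` — exactly for linear models and to quadrature accuracy
#' otherwise. Per-sample attributions are averaged across all supplied
#' samples, preserving sign.
#'
#' @param fit a `FitResult` holding an `ffnn_model` (masked or dense), or
#'   the model itself.
#' @param X numeric matrix (samples x features) to attribute.
#' @param background samples used to form the baseline; default the first
#'   100 rows of `X` (fewer if `X` is smaller).
#' @param steps number of path steps (quadrature resolution).
#' @return an `ImportanceVector` of mean attributions; attributes
#'   `per_sample` (samples x features matrix) and `baseline`.
#' @export
deep_attribution <- function(fit, X, background = NULL, steps = 256L) {
  model <- if (inherits(fit, "FitResult")) fit$model else fit
  if (!inherits(model, "ffnn_model")) stop("not a fitted ffnn model")
  X <- X[, model$features, drop = FALSE]
  if (is.null(background))
    background <- X[seq_len(min(100L, nrow(X))), , drop = FALSE]
  else background <- background[, model$features, drop = FALSE]
  if (nrow(background) < 1) stop("background must contain >= 1 sample")
  baseline <- colMeans(background)
  diff <- sweep(X, 2L, baseline)
  acc <- matrix(0, nrow(X), ncol(X))
  for (j in seq_len(steps)) {
    alpha <- (j - 0.5) / steps
    pts <- sweep(diff * alpha, 2L, baseline, `+`)
    acc <- acc + .ffnn_raw_gradient(model, pts)
  }
  per_sample <- diff * (acc / steps)
  dimnames(per_sample) <- dimnames(X)
  avg <- colMeans(per_sample)
  out <- importance_vector(avg, method = "integrated_gradients",
                           background = sprintf("mean of %d background samples, %d path steps",
                                                nrow(background), steps))
  attr(out, "per_sample") <- per_sample
  attr(out, "baseline") <- baseline
  out
}

#' Top-n features by absolute importance
#'
#' @param imp an `ImportanceVector`.
#' @param n number of features (at most `length(imp)`).
#' @return a `FeatureSet` ordered by decreasing |importance|, ties broken
#'   by probe ID.
#' @export
top_n <- function(imp, n = 1000) {
  stopifnot(inherits(imp, "ImportanceVector"))
  if (n > length(imp)) stop("`n` exceeds the number of features")
  ord <- order(-abs(as.numeric(imp)), names(imp))
  feature_set(names(imp)[ord[seq_len(n)]],
              provenance = list(target = attr(imp, "method"), k = n,
                                scheme = "top_importance"))
}

#' Hypergeometric overlap test between two feature sets
#'
#' Upper-tail hypergeometric probability of observing at least the seen
#' overlap between two sets drawn from a common universe.
#'
#' @param setA,setB character vectors (or `FeatureSet`s).
#' @param universe universe size (both sets must fit inside it).
#' @return list with `overlap` and `p`.
#' @examples
#' set_overlap_test(letters[1:5], letters[1:5], 20)  # p = 1/choose(20,5)
#' @export
set_overlap_test <- function(setA, setB, universe) {
  a <- unique(as.character(setA)); b <- unique(as.character(setB))
  if (length(a) > universe || length(b) > universe)
    stop("set size exceeds universe")
  k <- length(intersect(a, b))
  p <- stats::phyper(k - 1, length(a), universe - length(a), length(b),
                     lower.tail = FALSE)
  list(overlap = k, p = p)
}

#' Exclusive intersection counts for named sets
#'
#' Counts the elements of the union falling in each exclusive membership
#' pattern (the numbers behind an UpSet plot). Patterns are named by the
#' `&`-joined member sets; counts sum to the union size.
#'
#' @param sets named list of character vectors (>= 2 sets).
#' @return data.frame with `pattern` and `count`, largest first.
#' @export
intersection_counts <- function(sets) {
  if (length(sets) < 2 || is.null(names(sets)))
    stop("need >= 2 named sets")
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1L, function(m)
    paste(names(sets)[m], collapse = "&"))
  tab <- table(pattern)
  out <- data.frame(pattern = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$pattern), , drop = FALSE]
}

.hyper_upper <- function(k, K, n, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set overrepresentation analysis for top CpGs
#'
#' Maps the top CpGs to their annotated genes (each gene counted once per
#' hit list, regardless of how many probes carry it), then tests every set
#' in a collection by the upper-tail hypergeometric distribution against
#' the universe of genes annotated to any probe in the bundle.
#' Benjamini-Hochberg adjustment is applied across the collection;
#' conventionally, terms with FDR < 0.1 are called significant.
#'
#' @param top a `FeatureSet` (or character vector) of top CpGs.
#' @param ann an `AnnotationBundle`.
#' @param collection collection name in `ann$collections`.
#' @return An `EnrichmentTable` data.frame: `term`, `k` (hits), `n` (genes
#'   drawn), `K` (set size in universe), `N` (universe size), `p`, `fdr`;
#'   ordered by p. The universe description is attached as an attribute.
#' @export
ora_genesets <- function(top, ann, collection) {
  stopifnot(inherits(ann, "AnnotationBundle"))
  if (!collection %in% names(ann$collections))
    stop(sprintf("collection '%s' not in annotation bundle", collection))
  sets <- ann$collections[[collection]]
  universe <- sort(unique(unlist(ann$probe_gene, use.names = FALSE)))
  if (!length(universe)) stop("annotation bundle maps no probe to a gene")
  top_genes <- unique(unlist(ann$probe_gene[as.character(top)],
                             use.names = FALSE))
  top_genes <- intersect(top_genes, universe)
  if (!length(top_genes))
    stop("no top probe carries a gene annotation")
  N <- length(universe); n <- length(top_genes)
  rows <- lapply(names(sets), function(nm) {
    set_u <- intersect(sets[[nm]], universe)
    K <- length(set_u)
    k <- length(intersect(top_genes, set_u))
    data.frame(term = nm, k = k, n = n, K = K, N = N,
               p = .hyper_upper(k, K, n, N), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$fdr <- stats::p.adjust(tab$p, method = "BH")
  tab <- tab[order(tab$p, tab$term), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "universe") <- sprintf("%d genes annotated to any probe", N)
  class(tab) <- c("EnrichmentTable", "data.frame")
  tab
}

#' Genomic-feature enrichment for top CpGs
#'
#' Tests each CpG-island relation category and each regulatory-group
#' category for overrepresentation among the top CpGs versus the whole
#' array background, by the upper-tail hypergeometric distribution, with
#' Benjamini-Hochberg adjustment across all categories.
#'
#' @param top a `FeatureSet` (or character vector) of top CpGs.
#' @param ann an `AnnotationBundle` with island / regulatory-group
#'   categories for every probe.
#' @return An `EnrichmentTable` data.frame with a `family` column
#'   (`island` or `reggroup`) plus `term`, `k`, `n`, `K`, `N`, `p`, `fdr`.
#' @export
genomic_feature_enrichment <- function(top, ann) {
  stopifnot(inherits(ann, "AnnotationBundle"))
  top <- as.character(top)
  N <- length(ann$probe_island)
  n <- length(top)
  one_family <- function(cats, family) {
    lv <- sort(unique(unname(cats)))
    do.call(rbind, lapply(lv, function(cat) {
      K <- sum(cats == cat)
      k <- sum(cats[top] == cat)
      data.frame(family = family, term = cat, k = k, n = n, K = K, N = N,
                 p = .hyper_upper(k, K, n, N), stringsAsFactors = FALSE)
    }))
  }
  tab <- rbind(one_family(ann$probe_island, "island"),
               one_family(ann$probe_reggroup, "reggroup"))
  tab$fdr <- stats::p.adjust(tab$p, method = "BH")
  tab <- tab[order(tab$p, tab$term), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("EnrichmentTable", "data.frame")
  tab
}

#' Write an enrichment table as TSV
#'
#' @param tab an `EnrichmentTable`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
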