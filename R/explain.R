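#' Build connectivity masks for a biology-guided sparse network
#'
#' Derives the two binary connectivity matrices of the explainable aging
#' clock from an annotation bundle: CpG x gene (1 iff the probe is
#' annotated to the gene) and gene x gene-set (1 iff the gene belongs to
#' the set). CpGs without gene annotation are dropped; genes absent from
#' every set, and sets with no retained gene, are pruned (such nodes could
#' not influence the output and would only inflate the control network's
#' width). Multi-gene probes fan out to all their annotated genes.
#'
#' @param features a `FeatureSet` (or character vector) of selected CpGs.
#' @param ann an `AnnotationBundle` with gene-set `collections`.
#' @param collection name of the collection to use (e.g. `"pathways"`).
#' @return A `MaskSpec`: list with `cpg_gene` (retained CpGs x genes 0/1
#'   matrix), `gene_set` (genes x sets 0/1 matrix), `retained_cpgs`,
#'   `genes`, `set_names`, and `counts` (probes in/retained, genes, sets).
#' @export
build_masks <- function(features, ann, collection) {
  stopifnot(inherits(ann, "AnnotationBundle"))
  if (!collection %in% names(ann$collections))
    stop(sprintf("collection '%s' not in annotation bundle", collection))
  sets <- ann$collections[[collection]]
  probes <- as.character(features)
  pg <- ann$probe_gene[probes]
  annotated <- probes[lengths(pg) > 0]
  if (!length(annotated)) stop("no selected CpG has a gene annotation")

  set_genes <- sort(unique(unlist(sets, use.names = FALSE)))
  # genes must be reachable from a retained CpG AND belong to >= 1 set
  cpg_genes <- sort(unique(unlist(ann$probe_gene[annotated],
                                  use.names = FALSE)))
  genes <- intersect(cpg_genes, set_genes)
  if (!length(genes)) stop("no annotated gene belongs to any set")
  # drop CpGs all of whose genes were pruned
  keep <- vapply(annotated,
                 function(p) any(ann$probe_gene[[p]] %in% genes),
                 logical(1))
  retained <- annotated[keep]
  if (!length(retained)) stop("zero retained probes after pruning")

  cpg_gene <- matrix(0, length(retained), length(genes),
                     dimnames = list(retained, genes))
  for (p in retained) {
    g <- intersect(ann$probe_gene[[p]], genes)
    cpg_gene[p, g] <- 1
  }
  gene_set_full <- vapply(sets, function(s) as.numeric(genes %in% s),
                          numeric(length(genes)))
  if (is.null(dim(gene_set_full)))
    gene_set_full <- matrix(gene_set_full, nrow = length(genes))
  dimnames(gene_set_full) <- list(genes, names(sets))
  keep_sets <- colSums(gene_set_full) > 0
  gene_set <- gene_set_full[, keep_sets, drop = FALSE]

  structure(list(cpg_gene = cpg_gene, gene_set = gene_set,
                 retained_cpgs = retained, genes = genes,
                 set_names = colnames(gene_set),
                 counts = c(probes_in = length(probes),
                            probes_retained = length(retained),
                            genes = length(genes),
                            sets = ncol(gene_set))),
            class = "MaskSpec")
}

#' @export
print.MaskSpec <- function(x, ...) {
  cat(sprintf("MaskSpec: %d/%d CpGs retained -> %d genes -> %d sets\n",
              x$counts["probes_retained"], x$counts["probes_in"],
              x$counts["genes"], x$counts["sets"]))
  invisible(x)
}

#' Train the biology-masked explainable age regressor
#'
#' A feed-forward network whose layers are CpG -> gene -> gene set ->
#' age, with connectivity restricted to the annotation-derived masks:
#' weights (and their gradients) at mask-zero positions are multiplied by
#' the mask after every optimizer step, so they are exactly zero
#' throughout training. Each hidden neuron is a named gene or gene set,
#' which is what makes the fitted clock explainable. ReLU follows the gene
#' and the set layer; the final readout is linear.
#'
#' @param X numeric matrix (samples x CpGs) covering
#'   `masks$retained_cpgs`.
#' @param y numeric age target.
#' @param masks a `MaskSpec` from [build_masks()].
#' @param cfg a [train_config()].
#' @return A `FitResult` as in [train_ffnn_cv()]; the model additionally
#'   carries `masks` and `set_names`, and the training history records the
#'   maximum absolute masked-zero weight at every checkpoint.
#' @export
train_masked_ffnn <- function(X, y, masks, cfg = train_config()) {
  stopifnot(inherits(masks, "MaskSpec"), inherits(cfg, "train_config"))
  if (!all(masks$retained_cpgs %in% colnames(X)))
    stop("X does not cover masks$retained_cpgs")
  X <- X[, masks$retained_cpgs, drop = FALSE]
  mask_list <- list(masks$cpg_gene, masks$gene_set, NULL)
  hidden <- c(ncol(masks$cpg_gene), ncol(masks$gene_set))
  fold <- make_folds(length(y), cfg$folds, seed = cfg$seed)
  oof <- rep(NA_real_, length(y))
  for (f in seq_len(cfg$folds)) {
    tr <- fold != f
    m <- .ffnn_fit_one(X[tr, , drop = FALSE], y[tr], hidden, cfg,
                       masks = mask_list, seed = cfg$seed + f)
    oof[!tr] <- predict(m, X[!tr, , drop = FALSE])
  }
  final <- .ffnn_fit_one(X, y, hidden, cfg, masks = mask_list,
                         seed = cfg$seed)
  final$set_names <- masks$set_names
  final$mask_spec <- masks
  structure(list(model = final, features = colnames(X), oof = oof, y = y,
                 fold = fold, metrics = regression_metrics(oof, y),
                 provenance = list(type = "masked_ffnn",
                                   hidden_sizes = hidden,
                                   counts = masks$counts,
                                   lr = cfg$lr, epochs = cfg$epochs,
                                   standardize = cfg$standardize,
                                   folds = cfg$folds, seed = cfg$seed)),
            class = "FitResult")
}

#' Train the fully connected control network
#'
#' Identical layer widths to the masked model (retained CpGs -> genes ->
#' sets -> 1) but with dense, unmasked connectivity. Serves as the
#' accuracy reference for the cost of imposing the biology-guided sparse
#' architecture.
#'
#' @inheritParams train_masked_ffnn
#' @return A `FitResult` as in [train_ffnn_cv()].
#' @export
train_control_ffnn <- function(X, y, masks, cfg = train_config()) {
  stopifnot(inherits(masks, "MaskSpec"), inherits(cfg, "train_config"))
  X <- X[, masks$retained_cpgs, drop = FALSE]
  hidden <- c(ncol(masks$cpg_gene), ncol(masks$gene_set))
  fit <- train_ffnn_cv(X, y, arch_spec("custom", hidden_sizes = hidden),
                       cfg)
  fit$provenance$type <- "control_ffnn"
  fit
}

#' Per-sample gene-set neuron activations
#'
#' Returns the post-ReLU values of the gene-set layer for each sample:
#' the per-sample "pathway weights" that make a prediction explainable.
#' For a zero input the activations equal the rectified layer biases.
#'
#' @param fit a `FitResult` from [train_masked_ffnn()] (or its `model`).
#' @param X numeric matrix (samples x CpGs) covering the model features.
#' @return numeric matrix, samples x gene sets, of class
#'   `PathwayActivations`.
#' @export
pathway_activations <- function(fit, X) {
  model <- if (inherits(fit, "FitResult")) fit$model else fit
  if (!inherits(model, "ffnn_model") || !isTRUE(model$masked))
    stop("pathway activations require a masked (explainable) model")
  Xs <- X[, model$features, drop = FALSE]
  Xs <- sweep(sweep(Xs, 2L, model$center), 2L, model$scale, `/`)
  fw <- .nn_forward(model$net, Xs, keep = TRUE)
  act <- fw$A[[3L]]   # post-ReLU set layer (A[[1]] = input, A[[2]] = genes)
  dimnames(act) <- list(rownames(X), model$set_names)
  structure(act, class = c("PathwayActivations", "matrix", "array"))
}

#' Top-weighted gene sets of an explainable model
#'
#' Ranks gene sets by the absolute weight connecting their neuron to the
#' age output, ties broken by set name.
#'
#' @param fit a `FitResult` from [train_masked_ffnn()] (or its `model`).
#' @param n number of sets to report.
#' @return data.frame with `set`, `weight`, `abs_weight`, ordered by
#'   decreasing `abs_weight`.
#' @export
top_weighted_sets <- function(fit, n = 10) {
  model <- if (inherits(fit, "FitResult")) fit$model else fit
  if (!inherits(model, "ffnn_model") || !isTRUE(model$masked))
    stop("top_weighted_sets requires a masked (explainable) model")
  w <- as.numeric(model$net$W[[length(model$net$W)]])
  df <- data.frame(set = model$set_names, weight = w,
                   abs_weight = abs(w), stringsAsFactors = FALSE)
  df <- df[order(-df$abs_weight, df$set), ]
  rownames(df) <- NULL
  utils::head(df, n)
}
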