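# small annotation bundle built by hand: 10 probes, 6 annotated
hand_bundle <- function() {
  pg <- setNames(rep(list(character(0)), 10), sprintf("cg%02d", 1:10))
  pg[["cg01"]] <- "G1"; pg[["cg02"]] <- "G2"; pg[["cg03"]] <- "G3"
  pg[["cg04"]] <- c("G1", "G4"); pg[["cg05"]] <- "G5"; pg[["cg06"]] <- "G2"
  structure(list(
    probe_gene = pg,
    probe_island = setNames(rep("Island", 10), names(pg)),
    probe_reggroup = setNames(rep("Unclassified", 10), names(pg)),
    collections = list(
      sets = list(S1 = c("G1", "G2"), S2 = c("G3", "G4", "G5"),
                  S3 = c("G1", "G5")))),
    class = "AnnotationBundle")
}

test_that("mask construction drops unannotated probes and unused nodes", {
  ann <- hand_bundle()
  masks <- build_masks(feature_set(sprintf("cg%02d", 1:10)), ann, "sets")
  expect_identical(sort(masks$retained_cpgs), sprintf("cg%02d", 1:6))
  expect_identical(unname(masks$counts["probes_retained"]), 6L)
  # every retained CpG row links to >= 1 gene; every set has >= 1 gene
  expect_true(all(rowSums(masks$cpg_gene) >= 1))
  expect_true(all(colSums(masks$gene_set) >= 1))
  # multi-gene probe fans out to all its genes
  expect_equal(sum(masks$cpg_gene["cg04", ]), 2)
  expect_error(build_masks(feature_set("cg07"), ann, "sets"), "annotation")
  expect_error(build_masks(feature_set("cg01"), ann, "missing"),
               "not in annotation")
})

test_that("a one-to-one probe-gene-set chain yields permutation matrices", {
  pg <- setNames(lapply(1:3, function(i) paste0("G", i)), paste0("cg", 1:3))
  ann <- structure(list(
    probe_gene = pg,
    probe_island = setNames(rep("Island", 3), names(pg)),
    probe_reggroup = setNames(rep("Unclassified", 3), names(pg)),
    collections = list(chain = list(S1 = "G1", S2 = "G2", S3 = "G3"))),
    class = "AnnotationBundle")
  masks <- build_masks(feature_set(paste0("cg", 1:3)), ann, "chain")
  expect_true(all(rowSums(masks$cpg_gene) == 1) &&
                all(colSums(masks$cpg_gene) == 1))
  expect_true(all(rowSums(masks$gene_set) == 1) &&
                all(colSums(masks$gene_set) == 1))
})

masked_fixture <- function(seed = 91, epochs = 150) {
  fx <- tiny_cohort(seed = seed)
  fs <- select_top_k(cpg_correlations(fx$m, fx$meta$age), 120)
  masks <- build_masks(fs, fx$ann, "pathways")
  cfg <- fast_cfg(seed = seed, epochs = epochs)
  fit <- train_masked_ffnn(unclass(fx$m), fx$meta$age, masks, cfg)
  list(fx = fx, fs = fs, masks = masks, cfg = cfg, fit = fit)
}

test_that("mask-zero weights are exactly zero at every training checkpoint", {
  mf <- masked_fixture()
  hist <- mf$fit$model$net$history
  expect_gt(length(hist$masked_max), 2)  # checked mid-training, not just at the end
  expect_true(all(hist$masked_max == 0))
  net <- mf$fit$model$net
  expect_identical(max(abs(net$W[[1]] * (1 - mf$masks$cpg_gene))), 0)
  expect_identical(max(abs(net$W[[2]] * (1 - mf$masks$gene_set))), 0)
})

test_that("masked forward pass equals an explicitly sparse reconstruction", {
  mf <- masked_fixture(epochs = 60)
  model <- mf$fit$model
  X <- unclass(mf$fx$m)[1:5, model$features, drop = FALSE]
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, `/`)
  # reconstruct the forward pass from the nonzero entries only
  sparse_layer <- function(A, W, b, mask, relu) {
    out <- matrix(0, nrow(A), ncol(W))
    nz <- which(if (is.null(mask)) W != 0 | TRUE else mask == 1,
                arr.ind = TRUE)
    for (r in seq_len(nrow(nz)))
      out[, nz[r, 2]] <- out[, nz[r, 2]] + A[, nz[r, 1]] * W[nz[r, 1], nz[r, 2]]
    out <- sweep(out, 2, b, `+`)
    if (relu) pmax(out, 0) else out
  }
  A <- sparse_layer(Xs, model$net$W[[1]], model$net$b[[1]],
                    mf$masks$cpg_gene, TRUE)
  A <- sparse_layer(A, model$net$W[[2]], model$net$b[[2]],
                    mf$masks$gene_set, TRUE)
  A <- sparse_layer(A, model$net$W[[3]], model$net$b[[3]], NULL, FALSE)
  expect_equal(as.numeric(A) + model$y_center,
               unname(predict(model, X)), tolerance = 1e-10)
})

test_that("the dense control matches layer sizes and exceeds the masked parameter count", {
  mf <- masked_fixture(epochs = 40)
  ctl <- train_control_ffnn(unclass(mf$fx$m), mf$fx$meta$age, mf$masks,
                            mf$cfg)
  expect_identical(ctl$provenance$hidden_sizes,
                   c(ncol(mf$masks$cpg_gene), ncol(mf$masks$gene_set)))
  expect_identical(ctl$model$features, mf$masks$retained_cpgs)
  dense_params <- sum(vapply(ctl$model$net$W, length, numeric(1)))
  masked_nonzero <- sum(mf$masks$cpg_gene) + sum(mf$masks$gene_set) +
    ncol(mf$masks$gene_set)
  expect_gt(dense_params, masked_nonzero)
  # seeded determinism of the control's out-of-fold predictions
  ctl2 <- train_control_ffnn(unclass(mf$fx$m), mf$fx$meta$age, mf$masks,
                             mf$cfg)
  expect_equal(ctl$oof, ctl2$oof, tolerance = 1e-12)
})

test_that("pathway activations read the set layer and respect mask locality", {
  fx <- tiny_cohort(seed = 93)
  fs <- select_top_k(cpg_correlations(fx$m, fx$meta$age), 120)
  masks <- build_masks(fs, fx$ann, "pathways")
  cfg <- train_config(lr = 0.01, epochs = 60, seed = 93,
                      standardize = FALSE, checkpoint_every = 20L)
  fit <- train_masked_ffnn(unclass(fx$m), fx$meta$age, masks, cfg)
  model <- fit$model
  # zero input: activations equal the rectified biases
  X0 <- matrix(0, 1, length(model$features),
               dimnames = list("z", model$features))
  act0 <- pathway_activations(fit, X0)
  b1 <- model$net$b[[1]]; b2 <- model$net$b[[2]]
  expect_equal(as.numeric(act0),
               as.numeric(pmax(pmax(b1, 0) %*% model$net$W[[2]] + b2, 0)),
               tolerance = 1e-12)
  # two samples differing only in the CpGs of one gene differ only in the
  # sets containing that gene
  # find a gene carried by a CpG annotated to that gene alone, so
  # locality is exact
  single <- rowSums(masks$cpg_gene) == 1
  expect_true(any(single))
  g <- which(masks$cpg_gene[which(single)[1], ] == 1)
  only_g <- rownames(masks$cpg_gene)[single & masks$cpg_gene[, g] == 1]
  X1 <- unclass(fx$m)[1, model$features, drop = FALSE]
  X2 <- X1
  X2[, only_g] <- X2[, only_g] + 5
  d <- abs(pathway_activations(fit, X2) - pathway_activations(fit, X1))
  sets_of_g <- masks$gene_set[g, ] == 1
  expect_true(all(d[, !sets_of_g] == 0))
  # dense model has no named set layer
  dense <- train_ffnn_cv(unclass(fx$m)[, masks$retained_cpgs],
                         fx$meta$age, arch_spec("custom", c(8L)),
                         fast_cfg(seed = 2, epochs = 30))
  expect_error(pathway_activations(dense, unclass(fx$m)), "masked")
})

test_that("top-weighted sets rank by |output weight| with name tie-breaks", {
  mf <- masked_fixture(epochs = 40)
  model <- mf$fit$model
  w <- as.numeric(model$net$W[[3]])
  tw <- top_weighted_sets(mf$fit, n = length(w))
  expect_identical(tw$set[1], model$set_names[which.max(abs(w))])
  expect_true(all(diff(tw$abs_weight) <= 1e-15))
  # one nonzero weight: that set ranks first
  m1 <- model
  m1$net$W[[3]][] <- 0
  m1$net$W[[3]][3, 1] <- -2
  expect_identical(top_weighted_sets(m1, 1)$set, model$set_names[3])
})

test_that("zeroing a set's output weight changes predictions only through that set", {
  mf <- masked_fixture(epochs = 60)
  model <- mf$fit$model
  X <- unclass(mf$fx$m)[1:10, model$features, drop = FALSE]
  act <- pathway_activations(model, X)
  s <- which.max(abs(as.numeric(model$net$W[[3]])))
  w_s <- model$net$W[[3]][s, 1]
  ablated <- model
  ablated$net$W[[3]][s, 1] <- 0
  # linear readout: the prediction shifts by exactly w_s * activation_s
  expect_equal(predict(ablated, X), predict(model, X) - w_s * act[, s],
               tolerance = 1e-10, ignore_attr = TRUE)
})
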