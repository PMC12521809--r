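# Shared fixtures: small synthetic cohorts and hand-built network models.

# quick cohort with planted signal at desk-test scale
tiny_cohort <- function(seed = 7, n = 120, p = 600, noise_sd = 0.5, ...) {
  cfg <- synth_config(n_samples = n, n_cpgs = p, n_genes = 60, n_sets = 10,
                      age_cpgs = round(p * 0.10), smoking_cpgs = round(p * 0.05),
                      bmi_cpgs = round(p * 0.05), alcohol_cpgs = round(p * 0.05),
                      ancestry_cpgs = round(p * 0.02),
                      noise_sd = noise_sd, seed = seed, ...)
  ann <- generate_annotation(cfg)
  coh <- generate_cohort(cfg, ann)
  list(cfg = cfg, ann = ann, beta = coh$beta, meta = coh$metadata,
       truth = coh$truth, m = beta_to_m(coh$beta))
}

# fast non-reference training protocol for small problems
fast_cfg <- function(seed = 3, epochs = 200, lr = 0.01, folds = 5) {
  train_config(lr = lr, epochs = epochs, folds = folds, seed = seed,
               checkpoint_every = 25L)
}

# hand-built single-layer (linear) model with known weights, no scaling
linear_ffnn <- function(w, b = 0) {
  p <- length(w)
  structure(list(
    net = list(W = list(matrix(w, p, 1L)), b = list(b),
               dims = c(p, 1L), masks = NULL),
    center = rep(0, p), scale = rep(1, p), y_center = 0,
    features = paste0("f", seq_len(p)), hidden_sizes = integer(0),
    masked = FALSE), class = "ffnn_model")
}

# hand-built 2-layer ReLU model with known weights, no scaling
two_layer_ffnn <- function(W1, b1, W2, b2 = 0) {
  structure(list(
    net = list(W = list(W1, matrix(W2, ncol(W1), 1L)), b = list(b1, b2),
               dims = c(nrow(W1), ncol(W1), 1L), masks = NULL),
    center = rep(0, nrow(W1)), scale = rep(1, nrow(W1)), y_center = 0,
    features = paste0("f", seq_len(nrow(W1))),
    hidden_sizes = ncol(W1), masked = FALSE), class = "ffnn_model")
}

# forward pass written independently of the package internals (oracle)
oracle_forward <- function(model, X) {
  W <- model$net$W; b <- model$net$b
  A <- X
  for (l in seq_along(W)) {
    Z <- A %*% W[[l]] + matrix(b[[l]], nrow(A), length(b[[l]]), byrow = TRUE)
    A <- if (l < length(W)) (Z + abs(Z)) / 2 else Z
  }
  as.numeric(A) + model$y_center
}

# upper-tail hypergeometric by direct evaluation of the counting formula
oracle_hyper_upper <- function(k, K, n, N) {
  i <- seq(max(k, 0), min(n, K))
  if (!length(i)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# confusion statistics recounted from label pairs, formulas written out
oracle_confusion <- function(y_true, y_pred, classes) {
  n <- length(y_true)
  acc <- sum(y_true == y_pred) / n
  pe <- 0
  for (cl in classes)
    pe <- pe + (sum(y_true == cl) / n) * (sum(y_pred == cl) / n)
  kappa <- if (abs(1 - pe) < 1e-12) 0 else (acc - pe) / (1 - pe)
  by_class <- lapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    fp <- sum(y_true != cl & y_pred == cl)
    tn <- n - tp - fn - fp
    c(sens = tp / (tp + fn), spec = tn / (tn + fp))
  })
  list(accuracy = acc, kappa = kappa,
       by_class = do.call(rbind, by_class))
}
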