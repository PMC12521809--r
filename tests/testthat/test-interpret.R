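test_that("impurity importance concentrates on the informative feature and sums to 1", {
  set.seed(101)
  n <- 200
  X <- cbind(A = rep(c(0, 1), each = n / 2),
             B = rnorm(n), C = rnorm(n), D = rnorm(n))
  rownames(X) <- paste0("s", 1:n)
  y <- ifelse(X[, "A"] == 1, "yes", "no")
  fit <- train_rf_cv(X, y, n_trees = 100, max_depth = 4, seed = 5)
  imp <- rf_importance(fit)
  expect_equal(sum(imp), 1, tolerance = 1e-12)
  expect_gt(imp["A"], 0.9)
  expect_identical(attr(imp, "method"), "impurity")
})

test_that("a duplicated informative feature splits the importance of the original", {
  set.seed(103)
  n <- 300
  a <- rnorm(n)
  y <- ifelse(a + rnorm(n, sd = 0.3) > 0, "hi", "lo")
  X1 <- cbind(A = a, N1 = rnorm(n), N2 = rnorm(n))
  X2 <- cbind(A = a, A2 = a, N1 = X1[, "N1"], N2 = X1[, "N2"])
  rownames(X1) <- rownames(X2) <- paste0("s", 1:n)
  i1 <- rf_importance(train_rf_cv(X1, y, n_trees = 200, max_depth = 5,
                                  seed = 7))
  i2 <- rf_importance(train_rf_cv(X2, y, n_trees = 200, max_depth = 5,
                                  seed = 7))
  expect_equal(unname(i2["A"] + i2["A2"]), unname(i1["A"]),
               tolerance = 0.2)
})

test_that("attribution of a linear model is the closed form w_i (x_i - baseline_i)", {
  w <- c(2, -1, 0.5, 3)
  model <- linear_ffnn(w, b = 1.5)
  set.seed(105)
  X <- matrix(rnorm(40), 10, 4, dimnames = list(paste0("s", 1:10),
                                                model$features))
  bg <- X[1:5, , drop = FALSE]
  att <- deep_attribution(model, X, background = bg, steps = 8)
  ps <- attr(att, "per_sample")
  closed <- sweep(X, 2, colMeans(bg)) %*% diag(w)
  expect_equal(unname(ps), unname(closed), tolerance = 1e-12)
  expect_equal(as.numeric(att), colMeans(closed), tolerance = 1e-12)
})

test_that("a constant model attributes zero everywhere", {
  model <- linear_ffnn(rep(0, 3), b = 7)
  X <- matrix(rnorm(30), 10, 3, dimnames = list(paste0("s", 1:10),
                                                model$features))
  att <- deep_attribution(model, X, steps = 4)
  expect_true(all(att == 0))
  expect_error(deep_attribution(model, X, background = X[0, , drop = FALSE]),
               ">= 1")
})

test_that("attribution satisfies completeness on a 2-layer network", {
  set.seed(107)
  W1 <- matrix(rnorm(4 * 6), 4, 6)
  model <- two_layer_ffnn(W1, b1 = rnorm(6), W2 = rnorm(6), b2 = 0.3)
  X <- matrix(rnorm(5 * 4, sd = 2), 5, 4,
              dimnames = list(paste0("s", 1:5), model$features))
  bg <- matrix(rnorm(8 * 4), 8, 4, dimnames = list(NULL, model$features))
  baseline <- colMeans(bg)
  f_x <- oracle_forward(model, X)
  f_b <- oracle_forward(model, matrix(baseline, 1))
  # keep samples whose output differs materially from the baseline, so the
  # relative completeness criterion is well conditioned
  keep <- abs(f_x - f_b) > 0.5
  expect_gte(sum(keep), 3)
  att <- deep_attribution(model, X[keep, , drop = FALSE],
                          background = bg, steps = 8192)
  ps <- attr(att, "per_sample")
  residual <- abs(rowSums(ps) - (f_x - f_b)[keep])
  expect_true(all(residual < 1e-3 * abs(f_x - f_b)[keep]))
})

test_that("top-n extraction matches brute force and handles ties by ID", {
  v <- importance_vector(setNames(c(0.5, -0.9, 0.5, 0.1),
                                  c("cgD", "cgA", "cgB", "cgC")),
                         method = "test")
  expect_identical(as.character(top_n(v, 4)),
                   c("cgA", "cgB", "cgD", "cgC"))  # |.| desc, ties by ID
  expect_identical(as.character(top_n(v, 2)), c("cgA", "cgB"))
  set.seed(109)
  v2 <- importance_vector(setNames(rnorm(100), sprintf("cg%03d", 1:100)),
                          method = "test")
  expect_setequal(as.character(top_n(v2, 30)),
                  names(sort(-abs(v2)))[1:30])
  # disjoint from the bottom set when there are no ties
  bottom <- names(sort(abs(v2)))[1:30]
  expect_length(intersect(as.character(top_n(v2, 30)), bottom), 0)
  expect_error(top_n(v2, 101), "exceeds")
})

test_that("set overlap test matches direct hypergeometric evaluation", {
  # identical sets of size 5 in a universe of 20
  r <- set_overlap_test(letters[1:5], letters[1:5], 20)
  expect_identical(r$overlap, 5L)
  expect_equal(r$p, 1 / choose(20, 5), tolerance = 1e-12)
  # disjoint sets: P(X >= 0) = 1
  r0 <- set_overlap_test(c("a", "b"), c("c", "d"), 10)
  expect_identical(r0$overlap, 0L)
  expect_equal(r0$p, 1)
  expect_error(set_overlap_test(letters[1:5], letters[1:3], 4), "universe")
})

test_that("hypergeometric upper tails match exhaustive counting on small urns", {
  for (N in c(5, 12, 20, 30)) {
    for (K in c(0, 2, N %/% 2, N)) {
      for (n in c(1, N %/% 3, N)) {
        for (k in 0:min(n, K)) {
          got <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
          expect_equal(got, oracle_hyper_upper(k, K, n, N),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("exclusive intersection counts cover every membership pattern", {
  # disjoint sets: two singleton patterns
  ic <- intersection_counts(list(A = c("x", "y"), B = c("z")))
  expect_setequal(ic$pattern, c("A", "B"))
  expect_equal(sum(ic$count), 3)
  # nested sets split exclusively
  ic2 <- intersection_counts(list(A = c("x", "y", "z"), B = c("y", "z")))
  expect_equal(ic2$count[ic2$pattern == "A"], 1L)
  expect_equal(ic2$count[ic2$pattern == "A&B"], 2L)
  # random sets vs brute-force enumeration
  set.seed(111)
  sets <- list(A = sample(letters, 10), B = sample(letters, 8),
               C = sample(letters, 12))
  ic3 <- intersection_counts(sets)
  uni <- unique(unlist(sets))
  expect_equal(sum(ic3$count), length(uni))
  for (el in uni) {
    pat <- paste(names(sets)[vapply(sets, function(s) el %in% s,
                                    logical(1))], collapse = "&")
    expect_true(pat %in% ic3$pattern)
  }
  expect_error(intersection_counts(list(A = "x")), ">= 2")
})

test_that("gene-set ORA flags a constructed signal set first", {
  fx <- tiny_cohort(seed = 113, n = 30, p = 200)
  ann <- fx$ann
  # build a top list whose genes are exactly one set's genes
  target_set <- ann$collections$pathways[[3]]
  carriers <- names(ann$probe_gene)[vapply(ann$probe_gene, function(g)
    length(g) > 0 && all(g %in% target_set), logical(1))]
  top <- feature_set(carriers)
  tab <- ora_genesets(top, ann, "pathways")
  expect_identical(tab$term[1], names(ann$collections$pathways)[3])
  expect_true(all(tab$fdr >= 0 & tab$fdr <= 1))
  # BH monotone non-decreasing in p-rank order
  expect_true(all(diff(tab$fdr[order(tab$p)]) >= -1e-15))
  expect_error(ora_genesets(top, ann, "nope"), "not in annotation")
})

test_that("ORA deduplicates genes and is invariant to probe order", {
  fx <- tiny_cohort(seed = 115, n = 30, p = 200)
  annotated <- names(fx$ann$probe_gene)[lengths(fx$ann$probe_gene) > 0]
  top <- annotated[1:30]
  t1 <- ora_genesets(feature_set(top), fx$ann, "pathways")
  t2 <- ora_genesets(feature_set(rev(top)), fx$ann, "pathways")
  expect_equal(t1, t2)
})

test_that("hypergeometric tail at the null expectation is at least one half", {
  # N=20, K=10, n=4: E[X] = 2; P(X >= 2) computed by direct counting
  p_direct <- oracle_hyper_upper(2, 10, 4, 20)
  expect_gte(p_direct, 0.5)
  expect_equal(phyper(1, 10, 10, 4, lower.tail = FALSE), p_direct,
               tolerance = 1e-12)
})

test_that("Benjamini-Hochberg adjustment follows the step-up definition", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  # flat fdr inherits from the smallest downstream p*m/i
  p <- c(0.001, 0.01, 0.5, 0.9)
  m <- 4
  stepup <- rev(cummin(rev(sort(p) * m / seq_len(m))))
  expect_equal(sort(p.adjust(p, method = "BH")), pmin(stepup, 1))
})

test_that("genomic feature enrichment matches direct tail evaluation", {
  fx <- tiny_cohort(seed = 117, n = 20, p = 100)
  probes <- names(fx$ann$probe_island)
  islands <- probes[fx$ann$probe_island == "Island"]
  top <- feature_set(islands[seq_len(min(10, length(islands)))])
  tab <- genomic_feature_enrichment(top, fx$ann)
  row <- tab[tab$family == "island" & tab$term == "Island", ]
  expect_equal(row$p,
               oracle_hyper_upper(row$k, row$K, row$n, row$N),
               tolerance = 1e-12)
  # drawing the entire array: every category tail probability is 1
  tab_all <- genomic_feature_enrichment(feature_set(probes), fx$ann)
  expect_true(all(tab_all$p == 1))
})
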