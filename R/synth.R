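#' Configuration for synthetic buccal-methylome cohorts
#'
#' Bundles every knob of the synthetic generator: cohort size, probe/gene/
#' gene-set universe, planted per-target CpG counts, effect sizes on the
#' M scale, M-scale noise, and batch structure. Defaults emulate a buccal
#' EPIC cohort of adults (ages 18-93, smoking prevalence ~23%, six
#' imbalanced race/ethnicity groups) at desk scale.
#'
#' Planted probes occupy fixed leading index blocks, in order: age,
#' smoking, BMI, alcohol, then one block per ancestry class. Signals are
#' added on the M scale (where downstream models train) and mapped back to
#' beta via the inverse logit-2 transform, so stored betas always lie in
#' (0, 1).
#'
#' @param n_samples,n_cpgs,n_genes,n_sets universe sizes (`n_sets` is per
#'   collection).
#' @param age_range length-2 numeric, years; low must be >= 18.
#' @param age_cpgs,smoking_cpgs,bmi_cpgs,alcohol_cpgs,ancestry_cpgs planted
#'   CpG counts per target (`ancestry_cpgs` is per ancestry class); zero
#'   disables a signal.
#' @param age_slope M units per year at planted age CpGs.
#' @param smoking_shift M-unit mean shift in smokers.
#' @param bmi_slope M units per BMI unit.
#' @param alcohol_slope M units per unit of the 0-1 alcohol score.
#' @param ancestry_shift M-unit per-class shift.
#' @param noise_sd Gaussian noise standard deviation on the M scale.
#' @param n_batches number of plates; labels assigned round-robin.
#' @param batch_shift M-scale plate offset applied to a probe subset
#'   (0 = no batch effect).
#' @param batch_probe_frac fraction of probes receiving the plate offset.
#' @param gene_fraction fraction of probes annotated to at least one gene.
#' @param nonlinear_age if `TRUE`, half of the planted age CpGs carry a
#'   thresholded (hinge) age component instead of a pure linear one.
#' @param plant_pathway if `TRUE`, all planted age CpGs are annotated to a
#'   dedicated gene group that forms one gene set (`"PLANTED_SET"`) in each
#'   collection, so pathway-recovery can be tested.
#' @param seed integer RNG seed; the same config is reproducible bit-for-bit.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_samples = 500, n_cpgs = 5000, n_genes = 400,
                         n_sets = 50, age_range = c(18, 93),
                         age_cpgs = 300, smoking_cpgs = 100, bmi_cpgs = 100,
                         alcohol_cpgs = 100, ancestry_cpgs = 40,
                         age_slope = 0.02, smoking_shift = 1.0,
                         bmi_slope = 0.05, alcohol_slope = 1.0,
                         ancestry_shift = 1.0, noise_sd = 0.5,
                         n_batches = 4, batch_shift = 0,
                         batch_probe_frac = 0.1, gene_fraction = 0.6,
                         nonlinear_age = FALSE, plant_pathway = FALSE,
                         seed = 1L) {
  cfg <- list(n_samples = n_samples, n_cpgs = n_cpgs, n_genes = n_genes,
              n_sets = n_sets, age_range = age_range,
              age_cpgs = age_cpgs, smoking_cpgs = smoking_cpgs,
              bmi_cpgs = bmi_cpgs, alcohol_cpgs = alcohol_cpgs,
              ancestry_cpgs = ancestry_cpgs,
              age_slope = age_slope, smoking_shift = smoking_shift,
              bmi_slope = bmi_slope, alcohol_slope = alcohol_slope,
              ancestry_shift = ancestry_shift, noise_sd = noise_sd,
              n_batches = n_batches, batch_shift = batch_shift,
              batch_probe_frac = batch_probe_frac,
              gene_fraction = gene_fraction,
              nonlinear_age = nonlinear_age, plant_pathway = plant_pathway,
              seed = as.integer(seed))
  for (f in c("n_samples", "n_cpgs", "n_genes", "n_sets", "n_batches"))
    if (length(cfg[[f]]) != 1 || !is.finite(cfg[[f]]) || cfg[[f]] < 1)
      stop(sprintf("`%s` must be a positive count", f))
  planted <- c("age_cpgs", "smoking_cpgs", "bmi_cpgs", "alcohol_cpgs",
               "ancestry_cpgs")
  for (f in planted)
    if (length(cfg[[f]]) != 1 || !is.finite(cfg[[f]]) || cfg[[f]] < 0)
      stop(sprintf("`%s` must be a nonnegative count", f))
  total_planted <- cfg$age_cpgs + cfg$smoking_cpgs + cfg$bmi_cpgs +
    cfg$alcohol_cpgs + 5L * cfg$ancestry_cpgs
  if (total_planted > cfg$n_cpgs)
    stop("planted CpG counts exceed n_cpgs")
  for (f in c("age_slope", "smoking_shift", "bmi_slope", "alcohol_slope",
              "ancestry_shift", "noise_sd", "batch_shift"))
    if (!is.finite(cfg[[f]]))
      stop(sprintf("`%s` must be finite", f))
  if (cfg$noise_sd < 0) stop("`noise_sd` must be nonnegative")
  if (length(age_range) != 2 || age_range[1] >= age_range[2])
    stop("`age_range` must be an increasing (low, high) pair")
  if (age_range[1] < 18)
    stop("`age_range` low end must be >= 18 (adult cohort)")
  if (gene_fraction < 0 || gene_fraction > 1)
    stop("`gene_fraction` must be in [0, 1]")
  class(cfg) <- "synth_config"
  cfg
}

# ancestry class labels with proportions mirroring a large, imbalanced
# US buccal cohort (counts 960/114/869/204/5378/519 rescaled)
.ethnicity_levels <- c("Asian or Pacific Islander", "Black or African American",
                       "Hispanic or Latino", "Middle Eastern or North African",
                       "White or Caucasian", "Other")
.ethnicity_props <- c(960, 114, 869, 204, 5378, 519) / 8045

.island_levels <- c("Island", "N_Shelf", "N_Shore", "OpenSea", "S_Shelf",
                    "S_Shore")
.island_props <- c(0.31, 0.05, 0.12, 0.38, 0.04, 0.10)

.reggroup_levels <- c("Gene_associated", "Gene_Associated_Cell_type_specific",
                      "NonGene_Associated",
                      "NonGene_Associated_Cell_type_specific",
                      "Promoter_associated",
                      "Promoter_associated_Cell_type_specific",
                      "Unclassified", "Unclassified_Cell_type_specific",
                      "unannotated")
.reggroup_props <- c(0.03, 0.01, 0.02, 0.01, 0.12, 0.02, 0.06, 0.04, 0.69)

#' Alcohol category labels (drinks per week), least to most
#' @export
alcohol_levels <- c("0", "1-4", "4-7", "8-14", "15+")

#' Planted probe index blocks for a config
#'
#' Planted probes occupy fixed leading blocks of the probe index in the
#' order age, smoking, BMI, alcohol, then ancestry class blocks.
#'
#' @param cfg a [synth_config()].
#' @return named list of integer index vectors (`age`, `smoking`, `bmi`,
#'   `alcohol`, `ancestry` — the latter a list per class).
#' @export
planted_blocks <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  pos <- 0L
  take <- function(k) {
    idx <- if (k > 0) seq.int(pos + 1L, pos + k) else integer(0)
    pos <<- pos + k
    idx
  }
  anc_classes <- setdiff(.ethnicity_levels, "Other")
  out <- list(age = take(cfg$age_cpgs), smoking = take(cfg$smoking_cpgs),
              bmi = take(cfg$bmi_cpgs), alcohol = take(cfg$alcohol_cpgs),
              ancestry = stats::setNames(
                lapply(anc_classes, function(cl) take(cfg$ancestry_cpgs)),
                anc_classes))
  out
}

#' Generate a synthetic CpG annotation bundle
#'
#' Produces probe-to-gene annotations, per-probe CpG-island relation and
#' regulatory-group categories, and named gene-set collections
#' (`pathways` and `tf_targets`). A fixed fraction of probes
#' (`cfg$gene_fraction`, rounded) carries at least one gene; every probe
#' carries exactly one island and one regulatory-group category.
#'
#' @param cfg a [synth_config()].
#' @return An `AnnotationBundle`: list with `probe_gene` (named list of
#'   character vectors, possibly empty), `probe_island`, `probe_reggroup`
#'   (named character vectors), and `collections` (named list of named
#'   lists of gene vectors).
#' @export
generate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_genes < cfg$n_sets)
    stop("n_genes < n_sets: cannot populate non-empty, distinct gene sets")
  set.seed(cfg$seed)
  probes <- sprintf("cg%07d", seq_len(cfg$n_cpgs))
  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))

  n_annot <- round(cfg$gene_fraction * cfg$n_cpgs)
  blocks <- planted_blocks(cfg)
  planted_genes <- character(0)
  if (cfg$plant_pathway && cfg$age_cpgs > 0) {
    n_pg <- min(20L, cfg$n_genes)
    planted_genes <- genes[seq_len(n_pg)]
    must <- blocks$age
    pool <- setdiff(seq_len(cfg$n_cpgs), must)
    extra <- max(0L, n_annot - length(must))
    annot_idx <- sort(c(must, sample(pool, min(extra, length(pool)))))
  } else {
    annot_idx <- sort(sample(cfg$n_cpgs, n_annot))
  }

  probe_gene <- stats::setNames(rep(list(character(0)), cfg$n_cpgs), probes)
  # with a planted pathway, the planted genes are reserved: only age-block
  # probes map to them and only the planted set contains them, so the
  # CpG -> gene -> set funnel is identifiable
  free_genes <- setdiff(genes, planted_genes)
  if (!length(free_genes)) free_genes <- genes
  n_per <- sample(1:3, length(annot_idx), replace = TRUE,
                  prob = c(0.7, 0.25, 0.05))
  for (i in seq_along(annot_idx)) {
    j <- annot_idx[i]
    if (cfg$plant_pathway && j %in% blocks$age) {
      probe_gene[[j]] <- sample(planted_genes, 1L)
    } else if (cfg$plant_pathway) {
      probe_gene[[j]] <- sample(free_genes, min(n_per[i], length(free_genes)))
    } else {
      probe_gene[[j]] <- sample(genes, n_per[i])
    }
  }

  probe_island <- stats::setNames(
    sample(.island_levels, cfg$n_cpgs, replace = TRUE, prob = .island_props),
    probes)
  probe_reggroup <- stats::setNames(
    sample(.reggroup_levels, cfg$n_cpgs, replace = TRUE,
           prob = .reggroup_props),
    probes)

  make_collection <- function(prefix) {
    sets <- vector("list", cfg$n_sets)
    names(sets) <- sprintf("%s_%03d", prefix, seq_len(cfg$n_sets))
    pool <- if (length(planted_genes)) free_genes else genes
    for (s in seq_len(cfg$n_sets)) {
      size <- min(length(pool), 5L + stats::rpois(1L, 15))
      sets[[s]] <- sort(sample(pool, size))
    }
    if (length(planted_genes)) {
      sets[[1L]] <- planted_genes
      names(sets)[1L] <- "PLANTED_SET"
    }
    sets
  }
  collections <- list(pathways = make_collection("PATHWAY"),
                      tf_targets = make_collection("TF"))

  structure(list(probe_gene = probe_gene, probe_island = probe_island,
                 probe_reggroup = probe_reggroup, collections = collections),
            class = "AnnotationBundle")
}

#' @export
print.AnnotationBundle <- function(x, ...) {
  n_ann <- sum(lengths(x$probe_gene) > 0)
  cat(sprintf("AnnotationBundle: %d probes (%d gene-annotated), collections: %s\n",
              length(x$probe_gene), n_ann,
              paste(sprintf("%s (%d sets)", names(x$collections),
                            lengths(x$collections)), collapse = ", ")))
  invisible(x)
}

#' Generate a synthetic buccal cohort
#'
#' Simulates sample metadata (age uniform on `cfg$age_range`, Bernoulli
#' smoking at ~23% prevalence, a five-level weekly-alcohol category binned
#' from a latent consumption, continuous BMI, six imbalanced
#' race/ethnicity classes, 0-1 lifestyle scores, cell fractions, and
#' round-robin plate labels) and a beta-value matrix. Signal is planted on
#' the M scale at the probe blocks of [planted_blocks()] — linear in age,
#' a mean shift for smokers, linear in BMI and in the 0-1 alcohol score,
#' and per-class shifts for ancestry — plus Gaussian M-noise, then mapped
#' to beta via the inverse M transform (so all betas are in (0, 1)).
#' When `cfg$batch_shift` is nonzero, a plate-dependent M offset is added
#' to a random probe subset.
#'
#' @param cfg a [synth_config()].
#' @param ann an `AnnotationBundle` from [generate_annotation()] (used for
#'   probe identity; must have at least as many probes as `cfg$n_cpgs`).
#' @return list with `beta` (a `MethylMatrix` in beta space), `metadata`
#'   (data.frame), and `truth` (baseline M values, planted blocks, and the
#'   per-target effect sizes actually used).
#' @export
generate_cohort <- function(cfg, ann) {
  stopifnot(inherits(cfg, "synth_config"), inherits(ann, "AnnotationBundle"))
  if (length(ann$probe_gene) < cfg$n_cpgs)
    stop("annotation bundle has fewer probes than cfg$n_cpgs")
  set.seed(cfg$seed + 1L)
  n <- cfg$n_samples
  p <- cfg$n_cpgs
  probes <- names(ann$probe_gene)[seq_len(p)]
  samples <- sprintf("S%05d", seq_len(n))

  age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
  sex <- sample(c("Male", "Female"), n, replace = TRUE,
                prob = c(0.519, 0.481))
  smoking <- stats::rbinom(n, 1L, 1832 / 8045)
  bmi <- pmin(pmax(stats::rnorm(n, 27.5, 5), 16), 50)
  ethnicity <- sample(.ethnicity_levels, n, replace = TRUE,
                      prob = .ethnicity_props)
  # latent weekly drinks: zero-inflated lognormal, then binned to the
  # five survey categories
  drinks <- ifelse(stats::runif(n) < 0.30, 0,
                   stats::rlnorm(n, meanlog = log(4), sdlog = 0.9))
  alcohol <- cut(drinks, breaks = c(-Inf, 0.5, 4, 7, 14, Inf),
                 labels = alcohol_levels)
  alcohol_score <- scale_alcohol(as.character(alcohol))
  lifestyle <- c("hf", "af", "st", "sl", "im", "ed", "so", "di", "ex")
  ls_mat <- matrix(stats::runif(n * length(lifestyle)), n,
                   dimnames = list(NULL, lifestyle))
  epithelial <- stats::rbeta(n, 20, 4)
  neutrophil <- (1 - epithelial) * stats::rbeta(n, 5, 5)
  other_immune <- 1 - epithelial - neutrophil
  batch <- sprintf("plate%02d", ((seq_len(n) - 1L) %% cfg$n_batches) + 1L)

  baseline <- stats::runif(p, -4, 4)
  m <- matrix(rep(baseline, each = n), n, p)
  blocks <- planted_blocks(cfg)

  sgn <- function(k) sample(c(-1, 1), k, replace = TRUE)
  if (length(blocks$age)) {
    s <- cfg$age_slope * sgn(length(blocks$age))
    if (cfg$nonlinear_age) {
      # second half of the block: hinge signal, flat until the age midpoint
      half <- length(blocks$age) %/% 2
      lin <- blocks$age[seq_len(length(blocks$age) - half)]
      hin <- setdiff(blocks$age, lin)
      mid <- mean(cfg$age_range)
      m[, lin] <- m[, lin] +
        outer(age - mean(age), s[seq_along(lin)])
      m[, hin] <- m[, hin] +
        outer(pmax(age - mid, 0), 2 * s[length(lin) + seq_along(hin)])
    } else {
      m[, blocks$age] <- m[, blocks$age] + outer(age, s)
    }
  }
  if (length(blocks$smoking))
    m[, blocks$smoking] <- m[, blocks$smoking] +
      outer(smoking, cfg$smoking_shift * sgn(length(blocks$smoking)))
  if (length(blocks$bmi))
    m[, blocks$bmi] <- m[, blocks$bmi] +
      outer(bmi - mean(bmi), cfg$bmi_slope * sgn(length(blocks$bmi)))
  if (length(blocks$alcohol))
    m[, blocks$alcohol] <- m[, blocks$alcohol] +
      outer(alcohol_score - mean(alcohol_score),
            cfg$alcohol_slope * sgn(length(blocks$alcohol)))
  for (cl in names(blocks$ancestry)) {
    idx <- blocks$ancestry[[cl]]
    if (length(idx))
      m[, idx] <- m[, idx] +
        outer(as.numeric(ethnicity == cl),
              cfg$ancestry_shift * sgn(length(idx)))
  }

  batch_probes <- integer(0)
  if (cfg$batch_shift != 0) {
    n_bp <- max(1L, round(cfg$batch_probe_frac * p))
    batch_probes <- sort(sample(p, n_bp))
    b_idx <- as.integer(factor(batch))
    offset <- cfg$batch_shift * (b_idx - (cfg$n_batches + 1) / 2)
    m[, batch_probes] <- m[, batch_probes] + offset
  }

  if (cfg$noise_sd > 0)
    m <- m + matrix(stats::rnorm(n * p, sd = cfg$noise_sd), n, p)

  beta <- 2^m / (1 + 2^m)
  dimnames(beta) <- list(samples, probes)

  metadata <- data.frame(
    sample_id = samples, age = age, sex = sex,
    smoking = ifelse(smoking == 1L, "Smoker", "Non-smoker"),
    alcohol_category = as.character(alcohol),
    alcohol_score = alcohol_score, bmi = bmi, ethnicity = ethnicity,
    ls_mat, epithelial = epithelial, neutrophil = neutrophil,
    otherImmune = other_immune, batch = batch,
    stringsAsFactors = FALSE)

  list(beta = methyl_matrix(beta, "beta"), metadata = metadata,
       truth = list(baseline_m = stats::setNames(baseline, probes),
                    blocks = blocks, batch_probes = batch_probes,
                    effects = cfg[c("age_slope", "smoking_shift", "bmi_slope",
                                    "alcohol_slope", "ancestry_shift")]))
}

#' Write and read gene-set collections in GMT format
#'
#' Standard GMT: one set per line — name, description, then tab-separated
#' gene symbols.
#'
#' @param collection named list of character gene vectors.
#' @param path file path.
#' @param description description field written for every set.
#' @return `read_gmt` returns a named list of gene vectors; `write_gmt`
#'   returns `path` invisibly.
#' @export
write_gmt <- function(collection, path, description = "synthetic") {
  stopifnot(is.list(collection), !is.null(names(collection)))
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, description, collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  sets
}

#' Write a probe manifest and metadata table
#'
#' The manifest is a TSV with columns `probe`, `genes` (semicolon-joined,
#' empty when unannotated), `island`, `reggroup`; metadata is plain CSV.
#'
#' @param ann an `AnnotationBundle`.
#' @param metadata cohort metadata data.frame.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(ann, path) {
  stopifnot(inherits(ann, "AnnotationBundle"))
  df <- data.frame(
    probe = names(ann$probe_gene),
    genes = vapply(ann$probe_gene, paste, character(1), collapse = ";"),
    island = unname(ann$probe_island),
    reggroup = unname(ann$probe_reggroup),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = character(0))
  pg <- strsplit(df$genes, ";", fixed = TRUE)
  pg <- lapply(pg, function(x) x[nzchar(x)])
  names(pg) <- df$probe
  structure(list(probe_gene = pg,
                 probe_island = stats::setNames(df$island, df$probe),
                 probe_reggroup = stats::setNames(df$reggroup, df$probe),
                 collections = list()),
            class = "AnnotationBundle")
}

#' @rdname write_manifest
#' @export
write_metadata_csv <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
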