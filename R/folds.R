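#' Cross-validation fold assignment
#'
#' Assigns each sample to exactly one of `k` folds. Fold sizes differ by
#' at most one overall; with `strata` supplied, samples are additionally
#' balanced within each stratum (shuffled within stratum, then dealt
#' cyclically with a counter that continues across strata, so both the
#' per-stratum and the global partition stay as even as possible).
#'
#' @param n number of samples, or `strata` a vector of stratum labels
#'   (length n).
#' @param k number of folds (>= 2).
#' @param seed integer RNG seed.
#' @param strata optional stratum labels (e.g. class labels for
#'   stratified classification folds).
#' @return integer vector of fold ids in 1..k, length n.
#' @export
make_folds <- function(n, k = 5, seed = 1L, strata = NULL) {
  k <- as.integer(k)
  if (k < 2) stop("`k` must be >= 2")
  if (!is.null(strata)) {
    if (length(strata) != n) stop("`strata` length must equal n")
  }
  if (n < k) stop("fewer samples than folds")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- integer(n)
  counter <- 0L
  groups <- if (is.null(strata)) list(seq_len(n)) else
    split(seq_len(n), as.character(strata))
  for (idx in groups) {
    idx <- if (length(idx) > 1) sample(idx) else idx
    fold[idx] <- ((counter + seq_along(idx) - 1L) %% k) + 1L
    counter <- counter + length(idx)
  }
  fold
}

# save/restore the global RNG state so helpers that seed internally do not
# perturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
}
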