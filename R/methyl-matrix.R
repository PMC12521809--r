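#' Sample-by-CpG methylation matrix
#'
#' A thin S3 container for a numeric matrix of methylation values with an
#' explicit value-space tag. Rows are samples, columns are CpG probes.
#' `space = "beta"` holds methylation fractions in \[0, 1\];
#' `space = "M"` holds the log2-odds transform, which must be finite.
#'
#' @param values numeric matrix, samples in rows and probes in columns.
#'   Must carry row names (sample IDs) and column names (probe IDs).
#' @param space `"beta"` or `"M"`.
#' @return An object of class `MethylMatrix`: the matrix itself with a
#'   `space` attribute.
#' @examples
#' x <- matrix(c(0.2, 0.8, 0.5, 0.5), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("cg1", "cg2")))
#' mm <- methyl_matrix(x, "beta")
#' methyl_space(mm)
#' @export
methyl_matrix <- function(values, space = c("beta", "M")) {
  space <- match.arg(space)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x probes)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample row names and probe column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample IDs")
  if (anyDuplicated(colnames(values)))
    stop("duplicate probe IDs")
  if (space == "beta") {
    if (any(values < 0 | values > 1, na.rm = FALSE))
      stop("beta values must lie in [0, 1]")
  } else {
    if (!all(is.finite(values)))
      stop("M values must be finite")
  }
  structure(values, space = space, class = c("MethylMatrix", "matrix", "array"))
}

#' @rdname methyl_matrix
#' @param x a `MethylMatrix`.
#' @export
methyl_space <- function(x) {
  stopifnot(inherits(x, "MethylMatrix"))
  attr(x, "space")
}

#' @rdname methyl_matrix
#' @export
probe_ids <- function(x) colnames(x)

#' @rdname methyl_matrix
#' @export
sample_ids <- function(x) rownames(x)

#' @export
print.MethylMatrix <- function(x, ...) {
  cat(sprintf("MethylMatrix [%s]: %d samples x %d probes\n",
              attr(x, "space"), nrow(x), ncol(x)))
  invisible(x)
}

# subsetting drops to a plain matrix unless both dims retained as matrix;
# re-tag when the result is still a matrix
#' @export
`[.MethylMatrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, space = attr(x, "space"),
                     class = c("MethylMatrix", "matrix", "array"))
  out
}

#' Read / write methylation matrices as TSV
#'
#' The on-disk dialect is probes x samples: probe IDs in the first column
#' (named `probe_id`), one column per sample. `read_methyl_tsv` transposes
#' back to the in-memory samples x probes orientation.
#'
#' @param x a `MethylMatrix`.
#' @param path file path.
#' @param space value space to tag the matrix read from disk.
#' @return `read_methyl_tsv` returns a `MethylMatrix`;
#'   `write_methyl_tsv` returns `path` invisibly.
#' @export
write_methyl_tsv <- function(x, path) {
  stopifnot(inherits(x, "MethylMatrix"))
  df <- data.frame(probe_id = colnames(x), t(unclass(x)), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_methyl_tsv
#' @export
read_methyl_tsv <- function(path, space = c("beta", "M")) {
  space <- match.arg(space)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  probes <- df[[1L]]
  mat <- t(as.matrix(df[, -1L, drop = FALSE]))
  colnames(mat) <- probes
  methyl_matrix(mat, space)
}
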