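#' @keywords internal
"_PACKAGE"

RNA_ALPHABET <- c("A", "C", "G", "U")

#' Canonicalize a nucleotide string to uppercase RNA
#'
#' DNA input is accepted (T is rewritten to U) and mixed case is uppercased.
#' Characters outside \{A, C, G, U\} after canonicalization are a hard error:
#' a seed or site window containing ambiguity codes has no defined match set.
#'
#' @param x character vector of nucleotide sequences.
#' @param what label used in error messages (e.g. the record id).
#' @return character vector over \{A, C, G, U\}.
#' @export
canonicalize_rna <- function(x, what = "sequence") {
  x <- chartr("acgut", "ACGUU", x)
  x <- chartr("T", "U", x)
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    offender <- gsub("[ACGU]", "", x[bad][1L])
    stop(sprintf("invalid character(s) '%s' in %s after RNA canonicalization",
                 substr(offender, 1L, 5L), what), call. = FALSE)
  }
  x
}

# Run expr with a local RNG state seeded by `seed`; the caller's
# .Random.seed is restored afterwards so generators have no global effect.
with_rng_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Write a data.frame as TSV (no quoting, no row names); creates parent dir.
write_tsv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

#' Quantile-normalize an expression matrix
#'
#' Thin wrapper around \code{limma::normalizeQuantiles} for callers whose
#' matrix is not already normalized. The differential-expression pipeline
#' otherwise assumes its input matrix is normalized (log2 scale).
#'
#' @param mat numeric matrix, features x samples.
#' @return matrix of the same shape with identical column distributions.
#' @export
quantile_normalize <- function(mat) {
  if (!requireNamespace("limma", quietly = TRUE))
    stop("quantile_normalize() requires the 'limma' package", call. = FALSE)
  out <- limma::normalizeQuantiles(as.matrix(mat))
  dimnames(out) <- dimnames(mat)
  out
}
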