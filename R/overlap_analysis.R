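#' Cosine similarity of two gene sets
#'
#' The shared-gene count divided by the square root of the product of the two
#' set sizes. Taking the square root damps the influence of miRNAs with
#' unusually large target sets and normalizes the score into \[0, 1\].
#'
#' @param set_a,set_b character vectors of gene ids (duplicates ignored).
#' @return numeric scalar in \[0, 1\].
#' @export
cosine_similarity <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  if (length(a) == 0L || length(b) == 0L)
    stop("cosine similarity is undefined for an empty set", call. = FALSE)
  length(intersect(a, b)) / sqrt(length(a) * length(b))
}

#' Jaccard similarity of two gene sets
#'
#' Intersection over union; provided alongside [cosine_similarity()] for
#' percent-overlap reporting (cosine >= Jaccard always).
#'
#' @inheritParams cosine_similarity
#' @return numeric scalar in \[0, 1\].
#' @export
jaccard_similarity <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  if (length(a) == 0L && length(b) == 0L)
    stop("Jaccard similarity is undefined for two empty sets", call. = FALSE)
  length(intersect(a, b)) / length(union(a, b))
}

#' Target-set overlap for every miRNA pair, annotated by seed mismatch class
#'
#' Joins a pairwise mismatch table with per-miRNA target sets and computes,
#' per pair, the set sizes, shared-gene count and cosine similarity. Pairs in
#' which either miRNA has an empty or missing target set are skipped with a
#' single summary warning (their count is returned in the
#' \code{n_skipped} attribute).
#'
#' @param target_sets named list of gene-id vectors keyed by miRNA id.
#' @param mismatch_table output of [build_mismatch_table()].
#' @return data.frame with columns \code{id_a}, \code{id_b},
#'   \code{mismatch_class}, \code{n_a}, \code{n_b}, \code{n_shared},
#'   \code{cosine}.
#' @export
overlap_by_mismatch_class <- function(target_sets, mismatch_table) {
  stopifnot(all(c("mirna_a", "mirna_b", "distance") %in% names(mismatch_table)))
  evaluable <- function(id) {
    !is.null(target_sets[[id]]) && length(target_sets[[id]]) > 0L
  }
  ok <- vapply(mismatch_table$mirna_a, evaluable, NA) &
        vapply(mismatch_table$mirna_b, evaluable, NA)
  n_skipped <- sum(!ok)
  if (n_skipped > 0L)
    warning(n_skipped, " pair(s) skipped: empty or missing target set",
            call. = FALSE)
  tab <- mismatch_table[ok, , drop = FALSE]
  res <- data.frame(
    id_a = tab$mirna_a,
    id_b = tab$mirna_b,
    mismatch_class = tab$distance,
    n_a = vapply(tab$mirna_a, function(id) length(unique(target_sets[[id]])), 0L),
    n_b = vapply(tab$mirna_b, function(id) length(unique(target_sets[[id]])), 0L),
    stringsAsFactors = FALSE
  )
  res$n_shared <- vapply(seq_len(nrow(res)), function(i)
    length(intersect(target_sets[[res$id_a[i]]], target_sets[[res$id_b[i]]])),
    0L)
  res$cosine <- res$n_shared / sqrt(res$n_a * res$n_b)
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Box-and-whisker summary of overlap values per mismatch class
#'
#' Quartiles use linear interpolation (\code{quantile} type 7); whiskers
#' follow the Tukey convention: the most extreme observed values within
#' 1.5 x IQR of the box. The class median is the headline statistic.
#'
#' @param values numeric vector of overlap scores.
#' @param classes grouping vector (seed mismatch class per value).
#' @param whisker_mult whisker reach as a multiple of the IQR.
#' @return data.frame with one row per non-empty class: \code{mismatch_class},
#'   \code{n_pairs}, \code{q1}, \code{median}, \code{q3},
#'   \code{whisker_low}, \code{whisker_high}.
#' @export
summarize_distribution <- function(values, classes, whisker_mult = 1.5) {
  stopifnot(length(values) == length(classes))
  keep <- !is.na(values)
  values <- values[keep]; classes <- classes[keep]
  if (length(values) == 0L)
    return(data.frame(mismatch_class = integer(), n_pairs = integer(),
                      q1 = numeric(), median = numeric(), q3 = numeric(),
                      whisker_low = numeric(), whisker_high = numeric()))
  groups <- split(values, classes)
  rows <- lapply(names(groups), function(cl) {
    v <- groups[[cl]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3L] - q[1L]
    lo_fence <- q[1L] - whisker_mult * iqr
    hi_fence <- q[3L] + whisker_mult * iqr
    data.frame(mismatch_class = utils::type.convert(cl, as.is = TRUE),
               n_pairs = length(v),
               q1 = q[1L], median = q[2L], q3 = q[3L],
               whisker_low = min(v[v >= lo_fence]),
               whisker_high = max(v[v <= hi_fence]))
  })
  out <- do.call(rbind, rows)
  out[order(out$mismatch_class), , drop = FALSE]
}

#' Chi-square comparison of overlap vs cost between two miRNA pairs
#'
#' Tests whether the proportion of shared ("overlap") versus non-shared
#' ("cost") genes differs between two miRNA pairs, as a Pearson chi-square
#' test of association on the 2x2 table
#' \code{rbind(pair1, pair2)} with rows (shared, cost), df = 1, no
#' continuity correction. The cost count of a pair is conventionally
#' \code{|union| - |intersection|} of its two gene sets (see
#' [overlap_cost_counts()]).
#'
#' @param pair1,pair2 length-2 numeric vectors \code{c(n_shared, n_cost)}.
#' @return list with \code{statistic}, \code{df}, \code{p_value}.
#' @export
chi_square_overlap <- function(pair1, pair2) {
  stopifnot(length(pair1) == 2L, length(pair2) == 2L)
  tab <- rbind(pair1, pair2)
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(tab) == 0))
    stop("both pairs must have a positive total count", call. = FALSE)
  if (any(colSums(tab) == 0))
    stop("degenerate table: a column total is zero", call. = FALSE)
  ht <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Overlap and cost counts for a pair of gene sets
#'
#' \code{n_shared = |A intersect B|}; \code{n_cost = |A union B| - |A
#' intersect B|}, the symmetric count of genes targeted by exactly one of the
#' two miRNAs (regulatory control lost or gained under the seed change).
#'
#' @inheritParams cosine_similarity
#' @return named numeric vector \code{c(n_shared, n_cost)} suitable for
#'   [chi_square_overlap()].
#' @export
overlap_cost_counts <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  shared <- length(intersect(a, b))
  c(n_shared = shared, n_cost = length(union(a, b)) - shared)
}
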