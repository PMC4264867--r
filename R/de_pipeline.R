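#' Remove features with too few present calls
#'
#' A feature is removed iff its fraction of "present" calls across ALL
#' samples (both groups pooled) is strictly less than \code{min_fraction};
#' a feature at exactly the threshold is kept. "Marginal" calls, if supplied,
#' should be coded as absent by the caller.
#'
#' @param mat numeric matrix, features x samples (assumed normalized, log2).
#' @param calls character/logical matrix of the same shape: "present"/"absent"
#'   (or TRUE/FALSE for present).
#' @param min_fraction minimum present fraction (default 0.5).
#' @return the matrix restricted to retained features.
#' @export
presence_filter <- function(mat, calls, min_fraction = 0.5) {
  mat <- as.matrix(mat)
  if (!all(dim(calls) == dim(mat)))
    stop("calls matrix shape does not match expression matrix", call. = FALSE)
  present <- if (is.logical(calls)) calls else calls == "present"
  frac <- rowMeans(present)
  mat[frac >= min_fraction, , drop = FALSE]
}

#' Drop features lacking a gene annotation
#'
#' @param mat numeric matrix with feature (probe-set) rownames.
#' @param probe_to_gene named character vector mapping feature id to gene
#'   symbol (may be partial), or a two-column data.frame
#'   (\code{probe_id}, \code{gene_symbol}).
#' @return the matrix restricted to annotated features.
#' @export
drop_unannotated <- function(mat, probe_to_gene) {
  mat <- as.matrix(mat)
  map <- as_probe_map(probe_to_gene)
  keep <- rownames(mat) %in% names(map)
  if (!any(keep)) warning("no annotated features remain", call. = FALSE)
  mat[keep, , drop = FALSE]
}

as_probe_map <- function(probe_to_gene) {
  if (is.data.frame(probe_to_gene)) {
    stopifnot(ncol(probe_to_gene) >= 2L)
    stats::setNames(as.character(probe_to_gene[[2L]]),
                    as.character(probe_to_gene[[1L]]))
  } else {
    stopifnot(!is.null(names(probe_to_gene)))
    probe_to_gene
  }
}

#' Read a probe-to-gene annotation map from TSV
#'
#' @param path two-column TSV with header (\code{probe_id},
#'   \code{gene_symbol}).
#' @return named character vector (probe id to gene symbol).
#' @export
read_probe_map <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  if (ncol(df) < 2L) stop("probe map must have two columns", call. = FALSE)
  as_probe_map(df)
}

#' Collapse probe sets to genes by maximal signal-to-noise ratio
#'
#' For each gene, keeps the single probe set maximizing
#' SNR = mean / sd across all samples pooled, and relabels the row by the
#' gene symbol. A probe with sd = 0 gets SNR = +Inf (constant probes win;
#' a warning is emitted). SNR ties break to the lexicographically smallest
#' probe id so the collapse is deterministic.
#'
#' @param mat numeric matrix of annotated features (rownames = probe ids).
#' @param probe_to_gene annotation map as in [drop_unannotated()]; every
#'   row of \code{mat} must be annotated.
#' @return gene-level matrix (rownames = gene symbols, sorted).
#' @export
snr_collapse <- function(mat, probe_to_gene) {
  mat <- as.matrix(mat)
  map <- as_probe_map(probe_to_gene)
  if (!all(rownames(mat) %in% names(map)))
    stop("snr_collapse() requires annotated features; run drop_unannotated()",
         call. = FALSE)
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1L, stats::sd)
  snr <- ifelse(sdv == 0, Inf, mu / sdv)
  if (any(sdv == 0))
    warning(sum(sdv == 0), " constant probe(s): SNR treated as +Inf",
            call. = FALSE)
  genes <- unname(map[rownames(mat)])
  ord <- order(genes, -snr, rownames(mat), method = "radix")
  first <- ord[!duplicated(genes[ord])]
  out <- mat[first, , drop = FALSE]
  rownames(out) <- genes[first]
  out[order(rownames(out), method = "radix"), , drop = FALSE]
}

# Pooled standard error s_i of the group-mean difference, and the raw
# mean difference, per feature. a = (1/n1 + 1/n2) / (n1 + n2 - 2).
sam_components <- function(mat, treated) {
  n1 <- sum(treated); n2 <- sum(!treated)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least two samples", call. = FALSE)
  m1 <- rowMeans(mat[, treated, drop = FALSE])
  m2 <- rowMeans(mat[, !treated, drop = FALSE])
  ss1 <- rowSums((mat[, treated, drop = FALSE] - m1)^2)
  ss2 <- rowSums((mat[, !treated, drop = FALSE] - m2)^2)
  a <- (1 / n1 + 1 / n2) / (n1 + n2 - 2)
  list(diff = m1 - m2, s = sqrt(a * (ss1 + ss2)))
}

as_treated <- function(mat, groups) {
  groups <- as.character(groups)
  if (length(groups) != ncol(mat))
    stop("groups length must equal the number of samples", call. = FALSE)
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exactly two groups are required", call. = FALSE)
  treated <- if (all(sort(lev) == c("control", "treated")))
    groups == "treated" else groups == lev[1L]
  treated
}

#' SAM-style relative difference statistic
#'
#' \code{d_i = (mean_treated - mean_control) / (s_i + s0)} with \code{s_i}
#' the pooled standard error of the mean difference and \code{s0} a fudge
#' factor stabilizing genes with small variance. \code{s0 = "auto"} uses the
#' median of all \code{s_i}.
#'
#' @param mat numeric matrix, features x samples.
#' @param groups character/factor of length ncol(mat) with two levels;
#'   levels "treated"/"control" are recognized, otherwise the first level
#'   encountered is taken as treated.
#' @param s0 non-negative numeric, or \code{"auto"}.
#' @return list with \code{d} (named per feature), \code{s}, \code{s0}.
#' @export
sam_statistic <- function(mat, groups, s0 = "auto") {
  mat <- as.matrix(mat)
  treated <- as_treated(mat, groups)
  comp <- sam_components(mat, treated)
  if (identical(s0, "auto")) s0 <- stats::median(comp$s)
  if (!is.numeric(s0) || s0 < 0)
    stop("s0 must be a non-negative number or \"auto\"", call. = FALSE)
  if (s0 == 0 && any(comp$s == 0))
    stop("zero-variance gene with s0 = 0; use s0 > 0 (e.g. s0 = \"auto\")",
         call. = FALSE)
  d <- comp$diff / (comp$s + s0)
  names(d) <- rownames(mat)
  list(d = d, s = comp$s, s0 = s0)
}

# All distinct assignments of n1 "treated" labels to n samples, as a
# logical matrix (n x n_assignments); sampled uniformly without replacement
# if there are more than max_n.
label_permutations <- function(n, n1, max_n) {
  total <- choose(n, n1)
  if (total < 2L)
    stop("fewer than 2 distinct group-label permutations possible",
         call. = FALSE)
  if (total <= max_n) {
    idx <- utils::combn(n, n1)
  } else {
    seen <- new.env(parent = emptyenv())
    cols <- vector("list", max_n)
    k <- 0L
    while (k < max_n) {
      cand <- sort(sample.int(n, n1))
      key <- paste(cand, collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      k <- k + 1L
      cols[[k]] <- cand
    }
    idx <- do.call(cbind, cols)
  }
  apply(idx, 2L, function(ix) seq_len(n) %in% ix)
}

#' SAM-style permutation test with empirical FDR control
#'
#' Computes the observed d statistic, builds null d distributions from
#' group-label permutations (all distinct assignments when there are at most
#' \code{n_permutations}, otherwise a uniform sample without replacement),
#' and calls genes at \code{|d| >= delta}. When \code{delta} is NULL it is
#' chosen as the smallest observed |d| value whose estimated FDR — the median
#' across permutations of the null exceedance count, divided by the observed
#' exceedance count — is at most \code{fdr_target}.
#'
#' @inheritParams sam_statistic
#' @param n_permutations maximum number of label permutations.
#' @param fdr_target target false discovery rate (default 0.02).
#' @param delta optional fixed threshold on |d| (overrides fdr_target search).
#' @param rng_seed seed for permutation sampling (only used when sampling).
#' @param null_summary \code{"median"} (SAM's median-based FDR) or
#'   \code{"q90"} (90th-percentile variant).
#' @return object of class \code{sam_result}: list with \code{d}, \code{s0},
#'   \code{n_permutations}, \code{delta}, \code{estimated_fdr},
#'   \code{significant} (logical, named), \code{direction}
#'   ("up"/"down"/NA per feature) and \code{fdr_curve} (data.frame of the
#'   delta search path).
#' @export
permutation_fdr <- function(mat, groups, s0 = "auto", n_permutations = 1000L,
                            fdr_target = 0.02, delta = NULL, rng_seed = NULL,
                            null_summary = c("median", "q90")) {
  null_summary <- match.arg(null_summary)
  summarize <- if (null_summary == "median") stats::median
               else function(x) stats::quantile(x, 0.9, names = FALSE)
  mat <- as.matrix(mat)
  treated <- as_treated(mat, groups)
  obs <- sam_statistic(mat, groups, s0 = s0)
  s0v <- obs$s0
  perms <- with_rng_seed(rng_seed,
    label_permutations(ncol(mat), sum(treated), n_permutations))
  null_abs_d <- apply(perms, 2L, function(tr) {
    comp <- sam_components(mat, tr)
    abs(comp$diff / (comp$s + s0v))
  })
  ad <- abs(obs$d)
  if (is.null(delta)) {
    cand <- sort(unique(ad))
    # exceedance counts at every candidate delta via sorted lookups:
    # count(x >= t) = N - #(x < t)
    n_called <- length(ad) - findInterval(cand, sort(ad), left.open = TRUE)
    null_counts <- apply(null_abs_d, 2L, function(col)
      nrow(null_abs_d) - findInterval(cand, sort(col), left.open = TRUE))
    null_summary_ct <- apply(null_counts, 1L, summarize)
    fdr <- null_summary_ct / n_called
    fdr_curve <- data.frame(delta = cand, n_called = n_called, fdr = fdr)
    pass <- which(fdr <= fdr_target)
    if (length(pass) > 0L) {
      delta <- cand[pass[1L]]
      estimated_fdr <- fdr[pass[1L]]
    } else {
      delta <- Inf
      estimated_fdr <- 0
    }
  } else {
    n_called <- sum(ad >= delta)
    estimated_fdr <- if (n_called == 0L) 0 else
      min(1, summarize(colSums(null_abs_d >= delta)) / n_called)
    fdr_curve <- data.frame(delta = delta, n_called = n_called,
                            fdr = estimated_fdr)
  }
  significant <- ad >= delta
  direction <- ifelse(significant, ifelse(obs$d > 0, "up", "down"), NA)
  structure(list(d = obs$d, s = obs$s, s0 = s0v,
                 n_permutations = ncol(perms), delta = delta,
                 estimated_fdr = min(1, estimated_fdr),
                 fdr_target = fdr_target,
                 significant = significant, direction = direction,
                 fdr_curve = fdr_curve),
            class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat("SAM permutation result\n")
  cat(sprintf("  features: %d   permutations: %d   s0: %.4g\n",
              length(x$d), x$n_permutations, x$s0))
  cat(sprintf("  delta: %.4g   estimated FDR: %.4g   significant: %d (%d up, %d down)\n",
              x$delta, x$estimated_fdr, sum(x$significant),
              sum(x$direction == "up", na.rm = TRUE),
              sum(x$direction == "down", na.rm = TRUE)))
  invisible(x)
}

#' Split a SAM result into up- and down-regulated gene lists
#'
#' @param sam_result object from [permutation_fdr()].
#' @param contrast label for the contrast (e.g. "miR-429 vs control").
#' @return object of class \code{de_gene_sets}: list with \code{contrast},
#'   \code{up}, \code{down} (disjoint sorted gene vectors) and
#'   \code{fdr_target}.
#' @export
de_gene_sets <- function(sam_result, contrast = "contrast") {
  stopifnot(inherits(sam_result, "sam_result"))
  genes <- names(sam_result$d)
  up <- sort(genes[sam_result$significant & sam_result$d > 0], method = "radix")
  down <- sort(genes[sam_result$significant & sam_result$d < 0],
               method = "radix")
  structure(list(contrast = contrast, up = up, down = down,
                 fdr_target = sam_result$fdr_target),
            class = "de_gene_sets")
}

#' Overlap between two differential-expression gene-set results
#'
#' \code{mode = "all"} computes cosine similarity on the combined up+down
#' sets; \code{mode = "directional"} tags each gene with its direction first,
#' so a gene up in one contrast and down in the other does not count as
#' shared.
#'
#' @param sets_a,sets_b \code{de_gene_sets} objects.
#' @param mode \code{"all"} or \code{"directional"}.
#' @return list with \code{n_a}, \code{n_b}, \code{n_shared}, \code{cosine},
#'   \code{jaccard}.
#' @export
de_overlap <- function(sets_a, sets_b, mode = c("all", "directional")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sets_a, "de_gene_sets"), inherits(sets_b, "de_gene_sets"))
  tag <- function(s) {
    if (mode == "all") c(s$up, s$down)
    else c(paste0("up:", s$up), paste0("down:", s$down))
  }
  a <- tag(sets_a); b <- tag(sets_b)
  if (length(a) == 0L || length(b) == 0L)
    stop("de_overlap() requires non-empty DE gene sets", call. = FALSE)
  list(n_a = length(a), n_b = length(b),
       n_shared = length(intersect(a, b)),
       cosine = cosine_similarity(a, b),
       jaccard = jaccard_similarity(a, b))
}

#' Read an expression matrix from TSV
#'
#' @param path TSV with a header row of sample ids; first column = feature id.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  df <- read_tsv(path)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- as.character(df[[1L]])
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("expression matrix contains missing values",
                       call. = FALSE)
  mat
}

#' Read sample group labels from a two-column TSV (sample_id, group)
#'
#' @param path TSV with header.
#' @param sample_ids sample order to align the labels to (e.g.
#'   \code{colnames} of the expression matrix).
#' @return character vector of group labels in \code{sample_ids} order.
#' @export
read_group_labels <- function(path, sample_ids) {
  df <- read_tsv(path, colClasses = "character")
  if (ncol(df) < 2L) stop("groups file must have two columns", call. = FALSE)
  idx <- match(sample_ids, df[[1L]])
  if (anyNA(idx))
    stop("groups file is missing sample(s): ",
         paste(utils::head(sample_ids[is.na(idx)], 3L), collapse = ", "),
         call. = FALSE)
  df[[2L]][idx]
}

#' Read a present/absent call matrix from TSV
#'
#' @param path TSV with a header row of sample ids; first column = feature id;
#'   cells "present"/"absent" (a "marginal" cell is coerced to absent).
#' @return character matrix aligned like an expression matrix.
#' @export
read_calls_matrix <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- as.character(df[[1L]])
  mat[mat == "marginal"] <- "absent"
  bad <- !(mat %in% c("present", "absent"))
  if (any(bad))
    stop("calls matrix contains values other than present/absent/marginal",
         call. = FALSE)
  mat
}

#' Write DE gene sets as a long TSV (contrast, direction, gene_id)
#' @param sets a \code{de_gene_sets} object.
#' @param path output file path.
#' @export
write_de_gene_sets <- function(sets, path) {
  df <- data.frame(
    contrast = sets$contrast,
    direction = c(rep("up", length(sets$up)), rep("down", length(sets$down))),
    gene_id = c(sets$up, sets$down),
    stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}
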