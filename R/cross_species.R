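#' Read a two-species ortholog map from TSV
#'
#' Expects a two-column TSV with a header (a BioMart-export style layout:
#' species-A gene id, species-B gene id). Duplicate identical rows collapse;
#' many-to-many relations are allowed but flagged with a warning.
#'
#' @param path TSV file path.
#' @return data.frame of class \code{ortholog_map} with columns
#'   \code{gene_a}, \code{gene_b}.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) <= 1L) {
    warning("empty ortholog map: ", path, call. = FALSE)
    return(ortholog_map(character(0), character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)[-1L]) {
    f <- fields[[i]]
    if (length(f) < 2L || any(f[1:2] == ""))
      stop("empty cell in ortholog map at line ", i, " of ", path,
           call. = FALSE)
  }
  a <- vapply(fields[-1L], `[`, "", 1L)
  b <- vapply(fields[-1L], `[`, "", 2L)
  ortholog_map(a, b)
}

#' Construct an ortholog map
#'
#' @param gene_a,gene_b equal-length character vectors of orthologous gene
#'   id pairs (species A, species B).
#' @return data.frame of class \code{ortholog_map}.
#' @export
ortholog_map <- function(gene_a, gene_b) {
  stopifnot(length(gene_a) == length(gene_b))
  df <- unique(data.frame(gene_a = as.character(gene_a),
                          gene_b = as.character(gene_b),
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  if (nrow(df) > 0L &&
      (anyDuplicated(df$gene_a) > 0L || anyDuplicated(df$gene_b) > 0L))
    warning("ortholog map contains one-to-many relations", call. = FALSE)
  class(df) <- c("ortholog_map", "data.frame")
  df
}

map_side_cols <- function(side) {
  side <- match.arg(side, c("a", "b"))
  if (side == "a") c(from = "gene_a", to = "gene_b")
  else c(from = "gene_b", to = "gene_a")
}

#' Restrict a gene set to genes with an ortholog
#'
#' @param genes character vector of gene ids.
#' @param map an \code{ortholog_map}.
#' @param side which species namespace \code{genes} belongs to
#'   (\code{"a"} or \code{"b"}).
#' @return the subset of \code{genes} with at least one ortholog.
#' @export
restrict_to_orthologs <- function(genes, map, side = "a") {
  stopifnot(inherits(map, "ortholog_map"))
  cols <- map_side_cols(side)
  genes[genes %in% map[[cols[["from"]]]]]
}

#' Map a gene set into the other species' namespace
#'
#' Each gene is replaced by all of its orthologs: one-to-many relations
#' expand (nothing that could carry true overlap is dropped) and many-to-one
#' relations merge under set semantics.
#'
#' @inheritParams restrict_to_orthologs
#' @return sorted character vector of ortholog gene ids.
#' @export
map_target_set <- function(genes, map, side = "a") {
  stopifnot(inherits(map, "ortholog_map"))
  cols <- map_side_cols(side)
  unmapped <- setdiff(genes, map[[cols[["from"]]]])
  if (length(unmapped) > 0L)
    stop("unmapped gene(s): ", paste(utils::head(unmapped, 3L), collapse = ", "),
         "; run restrict_to_orthologs() first", call. = FALSE)
  hit <- map[map[[cols[["from"]]]] %in% genes, , drop = FALSE]
  sort(unique(hit[[cols[["to"]]]]), method = "radix")
}

#' Intra- and inter-species target-set overlap report
#'
#' For each pair of miRNAs within a species, reports the intra-specific
#' cosine overlap of their target sets; for each miRNA present in both
#' species' panels, reports the inter-specific overlap of its two sets after
#' restricting both sides to orthologs and mapping species B into species A's
#' namespace (set \code{map_direction = "a_to_b"} to map the other way).
#' Comparisons with an empty post-restriction set are skipped with a warning.
#'
#' @param sets_a,sets_b named lists of gene-id vectors (miRNA id ->
#'   target set), in species A's and species B's gene namespaces. For
#'   inter-species rows the two lists are matched by shared miRNA names with
#'   any species prefix (text before the first '-') ignored.
#' @param map an \code{ortholog_map} between the two namespaces.
#' @param map_direction \code{"b_to_a"} (default) or \code{"a_to_b"}.
#' @return data.frame with columns \code{comparison}
#'   (\code{intra_a}/\code{intra_b}/\code{inter}), \code{id_a}, \code{id_b},
#'   \code{n_a}, \code{n_b}, \code{n_shared}, \code{cosine}.
#' @export
species_overlap_report <- function(sets_a, sets_b, map,
                                   map_direction = c("b_to_a", "a_to_b")) {
  map_direction <- match.arg(map_direction)
  stopifnot(inherits(map, "ortholog_map"))
  row_for <- function(comparison, id_a, id_b, ga, gb) {
    shared <- length(intersect(ga, gb))
    data.frame(comparison = comparison, id_a = id_a, id_b = id_b,
               n_a = length(ga), n_b = length(gb), n_shared = shared,
               cosine = shared / sqrt(length(ga) * length(gb)),
               stringsAsFactors = FALSE)
  }
  intra <- function(sets, label) {
    ids <- names(sets)
    if (length(ids) < 2L) return(NULL)
    idx <- utils::combn(length(ids), 2L)
    do.call(rbind, lapply(seq_len(ncol(idx)), function(k) {
      i <- idx[1L, k]; j <- idx[2L, k]
      if (length(sets[[i]]) == 0L || length(sets[[j]]) == 0L) return(NULL)
      row_for(label, ids[i], ids[j], unique(sets[[i]]), unique(sets[[j]]))
    }))
  }
  strip <- function(ids) sub("^[^-]*-", "", ids)
  common <- intersect(strip(names(sets_a)), strip(names(sets_b)))
  n_skipped <- 0L
  inter <- do.call(rbind, lapply(common, function(mir) {
    ia <- names(sets_a)[strip(names(sets_a)) == mir][1L]
    ib <- names(sets_b)[strip(names(sets_b)) == mir][1L]
    ga <- restrict_to_orthologs(unique(sets_a[[ia]]), map, side = "a")
    gb <- restrict_to_orthologs(unique(sets_b[[ib]]), map, side = "b")
    if (length(ga) == 0L || length(gb) == 0L) {
      n_skipped <<- n_skipped + 1L
      return(NULL)
    }
    if (map_direction == "b_to_a") gb <- map_target_set(gb, map, side = "b")
    else ga <- map_target_set(ga, map, side = "a")
    row_for("inter", ia, ib, ga, gb)
  }))
  if (n_skipped > 0L)
    warning(n_skipped, " inter-species comparison(s) skipped: ",
            "empty set after ortholog restriction", call. = FALSE)
  out <- rbind(intra(sets_a, "intra_a"), intra(sets_b, "intra_b"), inter)
  if (is.null(out))
    out <- data.frame(comparison = character(), id_a = character(),
                      id_b = character(), n_a = integer(), n_b = integer(),
                      n_shared = integer(), cosine = numeric())
  rownames(out) <- NULL
  out
}
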