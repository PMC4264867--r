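SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

#' Reverse complement of an RNA string
#'
#' Watson-Crick complement (A-U, C-G), reversed. Input is canonicalized
#' (T to U, uppercase) first.
#'
#' @param x character vector of RNA/DNA strings.
#' @return character vector of reverse complements (RNA alphabet).
#' @export
reverse_complement <- function(x) {
  x <- canonicalize_rna(x)
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    as.character(Biostrings::reverseComplement(Biostrings::RNAString(s)))
  }, "", USE.NAMES = FALSE)
}

# Complement (not reversed) of a single base.
complement_base <- function(b) chartr("ACGU", "UGCA", b)

# Classify every occurrence of the seed's 6mer core (reverse complement of
# seed positions 1-6) in a UTR by its flanks:
#   m8 flank present + A at position 1  -> 8mer
#   m8 flank only                       -> 7mer-m8
#   A1 flank only                       -> 7mer-A1
#   neither                             -> 6mer
# Returns data.frame(core_start, actual_type) for core match starts (1-based).
classify_core_matches <- function(core_starts, utr, m8_char) {
  L <- nchar(utr)
  if (length(core_starts) == 0L)
    return(data.frame(core_start = integer(), actual_type = character(),
                      stringsAsFactors = FALSE))
  has_m8 <- core_starts > 1L &
    substring(utr, core_starts - 1L, core_starts - 1L) == m8_char
  has_a1 <- core_starts + 6L <= L &
    substring(utr, core_starts + 6L, core_starts + 6L) == "A"
  actual <- ifelse(has_m8 & has_a1, "8mer",
            ifelse(has_m8, "7mer-m8",
            ifelse(has_a1, "7mer-A1", "6mer")))
  data.frame(core_start = core_starts, actual_type = actual,
             stringsAsFactors = FALSE)
}

# Site types subsumed by an actual match class (strongest first).
satisfied_types <- function(actual) {
  switch(actual,
         "8mer" = SITE_TYPES,
         "7mer-m8" = c("7mer-m8", "6mer"),
         "7mer-A1" = c("7mer-A1", "6mer"),
         "6mer" = "6mer")
}

# 1-based inclusive UTR window for a reported site type given its core start.
site_window <- function(type, p) {
  switch(type,
         "8mer" = c(p - 1L, p + 6L),
         "7mer-m8" = c(p - 1L, p + 5L),
         "7mer-A1" = c(p, p + 6L),
         "6mer" = c(p, p + 5L))
}

#' Find seed-complementary sites in one 3'UTR
#'
#' Scans the given (sense-strand mRNA) UTR for canonical seed-match site
#' types, defined against the reverse complement of the 7-nt seed:
#' \describe{
#'   \item{7mer-m8}{exact match to revcomp(seed), i.e. pairing to mature
#'     positions 2-8.}
#'   \item{7mer-A1}{match to revcomp(seed positions 1-6, mature 2-7)
#'     followed by an A in the UTR.}
#'   \item{8mer}{both the m8 match and the A1 anchor.}
#'   \item{6mer}{match to revcomp(seed positions 1-6) only.}
#' }
#' Overlapping windows are each reported. Each core occurrence is reported
#' once, as the strongest requested type it satisfies (so an 8mer site is
#' never additionally listed as its constituent 7mers).
#'
#' @param seed 7-nt seed string (mature positions 2-8).
#' @param utr UTR sequence (character scalar; T canonicalized to U).
#' @param site_types site classes to report; default excludes the weakly
#'   effective 6mer class.
#' @param gene_id optional gene id to include as a column.
#' @return data.frame with columns \code{gene_id} (if given),
#'   \code{site_type}, \code{start}, \code{end} (1-based inclusive UTR
#'   coordinates), ordered 5' to 3' by \code{start}.
#' @export
seed_match_sites <- function(seed, utr,
                             site_types = c("8mer", "7mer-m8", "7mer-A1"),
                             gene_id = NULL) {
  if (length(site_types) == 0L)
    stop("site_types must name at least one site class", call. = FALSE)
  site_types <- match.arg(site_types, SITE_TYPES, several.ok = TRUE)
  seed <- canonicalize_rna(seed, what = "seed")
  if (nchar(seed) != 7L) stop("seed must be 7 nt", call. = FALSE)
  utr <- canonicalize_rna(utr, what = "UTR")
  core <- reverse_complement(substr(seed, 1L, 6L))
  m8_char <- complement_base(substr(seed, 7L, 7L))
  hits <- Biostrings::matchPattern(core, Biostrings::RNAString(utr))
  cls <- classify_core_matches(Biostrings::start(hits), utr, m8_char)
  rows <- lapply(seq_len(nrow(cls)), function(i) {
    sat <- satisfied_types(cls$actual_type[i])
    rep_type <- sat[sat %in% site_types][1L]
    if (is.na(rep_type)) return(NULL)
    w <- site_window(rep_type, cls$core_start[i])
    data.frame(site_type = rep_type, start = w[1L], end = w[2L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(
    data.frame(site_type = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE))))
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(gene_id)) out <- cbind(gene_id = gene_id, out)
  out
}

#' Read a 3'UTR pool from FASTA
#'
#' @param path FASTA file of UTR sequences (sense strand, 5' to 3'); the
#'   header token before the first whitespace is the gene id.
#' @return named character vector of canonical RNA sequences, one per gene.
#' @export
read_utr_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, "", 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate gene id(s) in UTR FASTA: ", paste(dup, collapse = ", "),
         call. = FALSE)
  seqs <- canonicalize_rna(as.character(set), what = "UTR sequence")
  if (any(nchar(seqs) == 0L))
    stop("empty UTR sequence for gene '", ids[nchar(seqs) == 0L][1L], "'",
         call. = FALSE)
  names(seqs) <- ids
  seqs
}

# Count qualifying sites per gene for one seed across a whole UTR pool.
# Vectorized over genes with vmatchPattern; used by predict_targets and the
# synthetic-data validators. A core occurrence qualifies iff the strongest
# class it satisfies (by flank content) subsumes a requested type.
count_sites_pool <- function(seed, utrs, site_types) {
  core <- reverse_complement(substr(seed, 1L, 6L))
  m8_char <- complement_base(substr(seed, 7L, 7L))
  want6 <- "6mer" %in% site_types
  want7m8 <- "7mer-m8" %in% site_types
  want7a1 <- "7mer-A1" %in% site_types
  want8 <- "8mer" %in% site_types
  set <- Biostrings::RNAStringSet(utrs)
  starts <- Biostrings::startIndex(Biostrings::vmatchPattern(core, set))
  vapply(seq_along(utrs), function(i) {
    st <- starts[[i]]
    if (is.null(st) || length(st) == 0L) return(0L)
    u <- utrs[[i]]
    L <- nchar(u)
    has_m8 <- st > 1L & substring(u, st - 1L, st - 1L) == m8_char
    has_a1 <- st + 6L <= L & substring(u, st + 6L, st + 6L) == "A"
    sum(want6 | (want7m8 & has_m8) | (want7a1 & has_a1) |
        (want8 & has_m8 & has_a1))
  }, 0L)
}

#' Predict target sets by scanning UTRs for seed matches
#'
#' A gene enters a miRNA's target set iff its UTR carries at least
#' \code{min_sites} sites of the requested types for that miRNA's seed.
#' miRNAs with identical seeds necessarily receive identical target sets.
#'
#' @param panel a \code{mirna_panel}.
#' @param utrs named character vector of UTR sequences (see
#'   [read_utr_fasta()]).
#' @param site_types site classes that qualify a gene as targeted.
#' @param min_sites minimum number of qualifying sites.
#' @param start,end seed window in mature coordinates.
#' @return named list (one element per miRNA id) of sorted gene-id vectors;
#'   attribute \code{provenance} is \code{"scanned"}.
#' @export
predict_targets <- function(panel, utrs,
                            site_types = c("8mer", "7mer-m8", "7mer-A1"),
                            min_sites = 1L, start = 2L, end = 8L) {
  stopifnot(inherits(panel, "mirna_panel"), length(utrs) > 0L)
  site_types <- match.arg(site_types, SITE_TYPES, several.ok = TRUE)
  seeds <- extract_seed(panel, start = start, end = end)
  genes <- names(utrs)
  counts_by_seed <- lapply(unique(unname(seeds)), function(s)
    count_sites_pool(s, utrs, site_types))
  names(counts_by_seed) <- unique(unname(seeds))
  sets <- lapply(seq_len(nrow(panel)), function(i) {
    ct <- counts_by_seed[[seeds[[i]]]]
    sort(genes[ct >= min_sites], method = "radix")
  })
  names(sets) <- panel$id
  attr(sets, "provenance") <- "scanned"
  sets
}

#' Load per-miRNA target sets from a precomputed prediction table
#'
#' Two TSV dialects are supported:
#' \describe{
#'   \item{mirsvr}{columns \code{mirna_id}, \code{gene_symbol},
#'     \code{mirsvr_score} (header required). Records are kept iff their
#'     score is strictly less than \code{score_threshold}; the default -0.2
#'     is the stringency cut-off commonly used to minimize false positives
#'     on the mirSVR scale (more negative = stronger predicted repression).}
#'   \item{two_column}{columns \code{mirna_id}, \code{gene_symbol}; all
#'     records kept (TargetScan/PicTar-style lists).}
#' }
#' Duplicate (miRNA, gene) rows collapse to set membership.
#'
#' @param path TSV file with a header row.
#' @param dialect \code{"mirsvr"} or \code{"two_column"}.
#' @param score_threshold strict upper bound on the kept score (mirsvr only).
#' @return named list of sorted gene-id vectors; attribute
#'   \code{provenance} is \code{"table:<dialect>"}.
#' @export
load_prediction_table <- function(path, dialect = c("mirsvr", "two_column"),
                                  score_threshold = -0.2) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty prediction table: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  need <- if (dialect == "mirsvr") c("mirna_id", "gene_symbol", "mirsvr_score")
          else c("mirna_id", "gene_symbol")
  if (!all(need %in% header))
    stop("prediction table header must contain: ", paste(need, collapse = ", "),
         call. = FALSE)
  col <- match(need, header)
  keep_id <- character(0); keep_gene <- character(0)
  for (i in seq_along(fields)[-1L]) {
    f <- fields[[i]]
    if (length(f) < length(header) || any(f[col] == ""))
      stop("malformed prediction row at line ", i, " of ", path, call. = FALSE)
    if (dialect == "mirsvr") {
      score <- suppressWarnings(as.numeric(f[col[3L]]))
      if (!is.finite(score))
        stop("non-numeric mirsvr_score at line ", i, " of ", path,
             call. = FALSE)
      if (score >= score_threshold) next
    }
    keep_id <- c(keep_id, f[col[1L]])
    keep_gene <- c(keep_gene, f[col[2L]])
  }
  sets <- lapply(split(keep_gene, keep_id), function(g)
    sort(unique(g), method = "radix"))
  sets <- sets[order(names(sets), method = "radix")]
  attr(sets, "provenance") <- paste0("table:", dialect)
  sets
}

#' Read target sets from a long TSV (mirna_id, gene_id)
#' @param path TSV written by [write_target_sets()].
#' @return named list of sorted gene-id vectors.
#' @export
read_target_sets <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  stopifnot(all(c("mirna_id", "gene_id") %in% names(df)))
  sets <- lapply(split(df$gene_id, df$mirna_id), function(g)
    sort(unique(g), method = "radix"))
  sets[order(names(sets), method = "radix")]
}

#' Write target sets as a long TSV (mirna_id, gene_id)
#' @param sets named list of gene-id vectors.
#' @param path output file path.
#' @export
write_target_sets <- function(sets, path) {
  df <- data.frame(
    mirna_id = rep(names(sets), lengths(sets)),
    gene_id = unlist(sets, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}
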