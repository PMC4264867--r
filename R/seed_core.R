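#' Read a mature miRNA panel from FASTA
#'
#' Reads miRBase-style mature FASTA (plain or gzip). The header token before
#' the first whitespace becomes the miRNA id; the token prefix before the
#' first '-' is stored as the species prefix (e.g. "hsa"). Sequences are
#' canonicalized to uppercase RNA (T becomes U).
#'
#' @param path path to a FASTA file (optionally gzip-compressed).
#' @return data.frame of class \code{mirna_panel} with columns
#'   \code{id}, \code{species_prefix}, \code{sequence}.
#' @export
read_mature_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, "", 1L)
  if (any(ids == "" | is.na(ids)))
    stop("FASTA record with empty header in ", path, call. = FALSE)
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for record '", ids[nchar(seqs) == 0L][1L], "'",
         call. = FALSE)
  mirna_panel(ids, seqs)
}

#' Construct a mature miRNA panel
#'
#' @param id character vector of unique miRNA identifiers.
#' @param sequence character vector of mature sequences (RNA or DNA alphabet;
#'   canonicalized to RNA).
#' @return data.frame of class \code{mirna_panel}.
#' @export
mirna_panel <- function(id, sequence) {
  stopifnot(length(id) == length(sequence))
  dup <- unique(id[duplicated(id)])
  if (length(dup) > 0L)
    stop("duplicate miRNA id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  sequence <- canonicalize_rna(sequence, what = "mature sequence")
  panel <- data.frame(id = as.character(id),
                      species_prefix = sub("-.*$", "", id),
                      sequence = sequence,
                      stringsAsFactors = FALSE)
  class(panel) <- c("mirna_panel", "data.frame")
  panel
}

#' Extract the seed region of mature miRNA sequences
#'
#' The seed is the subsequence at 1-based mature positions \code{start} to
#' \code{end} inclusive (default 2-8, the canonical 7-nt seed at the 5' end
#' of the mature strand).
#'
#' @param x character vector of mature sequences, or a \code{mirna_panel}
#'   (in which case a named vector keyed by miRNA id is returned).
#' @param start,end 1-based inclusive mature coordinates of the seed window.
#' @return character vector of seeds of length \code{end - start + 1}.
#' @examples
#' extract_seed("UAAUACUGUCUGGUAAAACCGU")  # "AAUACUG" (miR-429)
#' @export
extract_seed <- function(x, start = 2L, end = 8L) {
  if (inherits(x, "mirna_panel")) {
    seqs <- x$sequence
    nm <- x$id
  } else {
    seqs <- canonicalize_rna(as.character(x), what = "mature sequence")
    nm <- names(x)
  }
  if (start < 1L || end < start)
    stop("invalid seed window: start=", start, ", end=", end, call. = FALSE)
  short <- nchar(seqs) < end
  if (any(short))
    stop("sequence shorter than seed end position ", end, ": ",
         paste(utils::head(if (is.null(nm)) seqs[short] else nm[short], 3L),
               collapse = ", "), call. = FALSE)
  out <- substr(seqs, start, end)
  names(out) <- nm
  out
}

#' Hamming distance between equal-length sequences
#'
#' Number of positions at which two sequences differ — the number of
#' nucleotide changes needed to transform one seed into the other.
#'
#' @param a,b character vectors of equal-length strings (recycled pairwise).
#' @return integer vector of distances.
#' @export
hamming_distance <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (any(la != lb))
    stop("hamming_distance() requires equal-length sequences", call. = FALSE)
  mapply(function(x, y) {
    sum(strsplit(x, "", fixed = TRUE)[[1L]] != strsplit(y, "", fixed = TRUE)[[1L]])
  }, a, b, USE.NAMES = FALSE)
}

#' Positions at which two seeds differ, in mature coordinates
#'
#' Seed index i (1-based within the seed) is reported as
#' \code{i + coordinate_offset - 1}, so with the default offset of 2 the
#' positions are 1-based mature-miRNA coordinates for a 2-8 seed window.
#'
#' @param a,b two seed strings of equal length.
#' @param coordinate_offset mature coordinate of the first seed position.
#' @return increasing integer vector of mature positions (empty if identical).
#' @export
mismatch_positions <- function(a, b, coordinate_offset = 2L) {
  if (nchar(a) != nchar(b))
    stop("mismatch_positions() requires equal-length sequences", call. = FALSE)
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  which(ca != cb) + as.integer(coordinate_offset) - 1L
}

#' Pairwise seed mismatch table for a miRNA panel
#'
#' Computes the seed Hamming distance for all n(n-1)/2 unordered pairs.
#' Pairs are ordered canonically (id_a < id_b lexicographically, C collation)
#' so the table is reproducible byte-for-byte.
#'
#' @param panel a \code{mirna_panel}.
#' @param start,end seed window (1-based inclusive mature coordinates).
#' @return data.frame with columns \code{mirna_a}, \code{mirna_b},
#'   \code{seed_a}, \code{seed_b}, \code{distance}.
#' @export
build_mismatch_table <- function(panel, start = 2L, end = 8L) {
  stopifnot(inherits(panel, "mirna_panel"))
  if (nrow(panel) < 2L)
    stop("panel must contain at least two miRNAs", call. = FALSE)
  seeds <- extract_seed(panel, start = start, end = end)
  ids <- panel$id
  ord <- order(ids, method = "radix")
  ids <- ids[ord]; seeds <- seeds[ord]
  idx <- utils::combn(length(ids), 2L)
  out <- data.frame(
    mirna_a = ids[idx[1L, ]],
    mirna_b = ids[idx[2L, ]],
    seed_a = unname(seeds[idx[1L, ]]),
    seed_b = unname(seeds[idx[2L, ]]),
    stringsAsFactors = FALSE
  )
  out$distance <- hamming_distance(out$seed_a, out$seed_b)
  out
}

#' Write a mismatch table to TSV
#' @param table output of [build_mismatch_table()].
#' @param path output file path.
#' @export
write_mismatch_table <- function(table, path) write_tsv(table, path)

#' Group a panel into identical-seed families
#'
#' Partitions the panel by exact seed string. A family of size k contributes
#' k(k-1)/2 identical-seed pairs to the mismatch-class-0 group.
#'
#' @inheritParams build_mismatch_table
#' @return named list mapping each seed string to the character vector of
#'   miRNA ids carrying it (ids sorted; families sorted by seed).
#' @export
group_identical_seeds <- function(panel, start = 2L, end = 8L) {
  stopifnot(inherits(panel, "mirna_panel"))
  seeds <- extract_seed(panel, start = start, end = end)
  fam <- split(panel$id, unname(seeds))
  fam <- lapply(fam, sort, method = "radix")
  fam[order(names(fam), method = "radix")]
}
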