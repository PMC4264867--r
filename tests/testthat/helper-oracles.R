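# Independent brute-force oracles, written from first principles and kept
# free of the package's own primitives.

# miRBase mature sequences used as worked examples throughout the suite
MIR429 <- "UAAUACUGUCUGGUAAAACCGU"
MIR141 <- "UAACACUGUCUGGUAAAGAUGG"
MIR205 <- "UCCUUCAUUCCACCGGAGUCUG"
MIR25  <- "CAUUGCACUUGUCUCGGUCUGA"
MIR32  <- "UAUUGCACAUUACUAAGUUGCA"

oracle_comp <- c(A = "U", C = "G", G = "C", U = "A")

oracle_revcomp <- function(s) {
  ch <- rev(strsplit(s, "")[[1]])
  paste(oracle_comp[ch], collapse = "")
}

oracle_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- 0L
  for (i in seq_along(ca)) if (ca[i] != cb[i]) n <- n + 1L
  n
}

random_seed_string <- function(len = 7) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# Naive all-windows site scan: enumerates every UTR position, tests window
# content against the literal patterns for each class, applies the
# strongest-requested-type precedence.
oracle_scan <- function(seed, utr, site_types = c("8mer", "7mer-m8", "7mer-A1")) {
  L <- nchar(utr)
  core <- oracle_revcomp(substr(seed, 1, 6))
  m8 <- oracle_comp[substr(seed, 7, 7)]
  out <- NULL
  for (i in seq_len(max(L - 5, 0))) {
    if (substr(utr, i, i + 5) != core) next
    has_m8 <- i > 1 && substr(utr, i - 1, i - 1) == m8
    has_a1 <- i + 6 <= L && substr(utr, i + 6, i + 6) == "A"
    sat <- c("6mer")
    if (has_m8) sat <- c("7mer-m8", sat)
    if (has_a1) sat <- c("7mer-A1", sat)
    if (has_m8 && has_a1) sat <- c("8mer", sat)
    sat <- intersect(c("8mer", "7mer-m8", "7mer-A1", "6mer"), sat)
    pick <- sat[sat %in% site_types]
    if (length(pick) == 0) next
    ty <- pick[1]
    w <- switch(ty,
                "8mer" = c(i - 1, i + 6), "7mer-m8" = c(i - 1, i + 5),
                "7mer-A1" = c(i, i + 6), "6mer" = c(i, i + 5))
    out <- rbind(out, data.frame(site_type = ty, start = w[1], end = w[2],
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(site_type = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  out[order(out$start, out$end), , drop = FALSE]
}

oracle_cosine <- function(a, b) {
  a <- unique(a); b <- unique(b)
  sum(a %in% b) / sqrt(length(a) * length(b))
}

# Closed-form Pearson chi-square over the four cells of a 2x2 table
oracle_chisq <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  e <- outer(rs, cs) / n
  sum((tab - e)^2 / e)
}

# Quartiles by the linear-interpolation formula h = (n-1)p + 1 directly
oracle_quartile <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

write_temp_fasta <- function(records, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}
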