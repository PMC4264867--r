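random_rna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(RNA_ALPHABET, len, replace = TRUE), collapse = ""), "")
}

mutate_seed <- function(seed, k, positions = NULL, seed_start = 2L) {
  ch <- strsplit(seed, "", fixed = TRUE)[[1L]]
  if (is.null(positions)) {
    idx <- sample.int(length(ch), k)
  } else {
    idx <- as.integer(positions) - seed_start + 1L
    if (length(idx) != k || any(idx < 1L | idx > length(ch)))
      stop("mismatch positions must lie in the seed window and match k",
           call. = FALSE)
  }
  for (i in idx) ch[i] <- sample(setdiff(RNA_ALPHABET, ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Generate a synthetic mature-miRNA panel with controlled seed mismatches
#'
#' Emulates construct design for seed-swap experiments: miRNA pairs named in
#' \code{mismatch_spec} receive seeds at exactly the requested Hamming
#' distance while sharing identical non-seed regions (so any downstream
#' difference is attributable to the seed); unconstrained miRNAs are fully
#' random.
#'
#' @param n panel size.
#' @param mismatch_spec list of constraints, each a list with elements
#'   \code{a}, \code{b} (miRNA ids), \code{k} (required seed Hamming
#'   distance, 0-7) and optionally \code{positions} (mature coordinates of
#'   the mismatches, e.g. \code{c(2,3,5,7,8)}).
#' @param ids miRNA identifiers (default \code{syn-miR-001} ...).
#' @param mature_length mature sequence length (default 22).
#' @param seed_start,seed_end seed window in mature coordinates.
#' @param rng_seed integer seed; the caller's RNG state is untouched.
#' @return list with \code{panel} (a \code{mirna_panel}) and \code{truth}
#'   (data.frame \code{id_a}, \code{id_b}, \code{k} of intended distances,
#'   plus the rng seed as an attribute).
#' @export
gen_mirna_panel <- function(n, mismatch_spec = list(),
                            ids = sprintf("syn-miR-%03d", seq_len(n)),
                            mature_length = 22L, seed_start = 2L,
                            seed_end = 8L, rng_seed = NULL) {
  stopifnot(n >= 1L, length(ids) == n, mature_length >= seed_end)
  seed_len <- seed_end - seed_start + 1L
  with_rng_seed(rng_seed, {
    seeds <- stats::setNames(rep(NA_character_, n), ids)
    nonseed_pre <- stats::setNames(random_rna(n, seed_start - 1L), ids)
    nonseed_post <- stats::setNames(random_rna(n, mature_length - seed_end), ids)
    for (spec in mismatch_spec) {
      a <- spec$a; b <- spec$b; k <- spec$k
      if (!all(c(a, b) %in% ids))
        stop("mismatch_spec names unknown miRNA id(s)", call. = FALSE)
      if (k < 0L || k > seed_len)
        stop("mismatch count k must be in [0, ", seed_len, "]", call. = FALSE)
      if (is.na(seeds[a]) && is.na(seeds[b]))
        seeds[a] <- paste(sample(RNA_ALPHABET, seed_len, replace = TRUE),
                          collapse = "")
      if (is.na(seeds[b])) {
        seeds[b] <- mutate_seed(seeds[a], k, spec$positions, seed_start)
        nonseed_pre[b] <- nonseed_pre[a]; nonseed_post[b] <- nonseed_post[a]
      } else if (is.na(seeds[a])) {
        seeds[a] <- mutate_seed(seeds[b], k, spec$positions, seed_start)
        nonseed_pre[a] <- nonseed_pre[b]; nonseed_post[a] <- nonseed_post[b]
      } else {
        got <- hamming_distance(seeds[a], seeds[b])
        if (got != k)
          stop("contradictory mismatch_spec: pair (", a, ", ", b,
               ") already constrained to distance ", got,
               ", requested ", k, call. = FALSE)
      }
    }
    free <- is.na(seeds)
    seeds[free] <- random_rna(sum(free), seed_len)
    sequences <- paste0(nonseed_pre, seeds, nonseed_post)
    truth <- if (length(mismatch_spec) > 0L) {
      data.frame(id_a = vapply(mismatch_spec, `[[`, "", "a"),
                 id_b = vapply(mismatch_spec, `[[`, "", "b"),
                 k = vapply(mismatch_spec, function(s) as.integer(s$k), 0L),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(id_a = character(), id_b = character(), k = integer())
    }
    list(panel = mirna_panel(ids, sequences), truth = truth)
  })
}

# The 8-nt window planted for a seed: complement of mature position 8,
# then revcomp of seed positions 1-6, then the A1 anchor. Classified as an
# 8mer site by seed_match_sites().
planted_pattern <- function(seed) {
  paste0(complement_base(substr(seed, 7L, 7L)),
         reverse_complement(substr(seed, 1L, 6L)), "A")
}

# Non-overlapping window starts: k sorted draws without replacement from a
# shrunk range, shifted so consecutive windows cannot collide.
draw_window_starts <- function(L, k, width = 8L) {
  if (k == 0L) return(integer(0))
  m <- L - (width - 1L) - width * (k - 1L)
  if (m < k)
    stop("site windows do not fit in utr_length; increase utr_length",
         call. = FALSE)
  sort(sample.int(m, k)) + width * (seq_len(k) - 1L)
}

# Validate a pool against planted truth: for every unique seed, the number
# of windows qualifying under the requested site types in every gene must
# equal the planted count. Planted windows are written verbatim (and always
# qualify), so count equality implies zero off-target sites.
# expected: data.frame(seed, gene_id, n_sites); unlisted genes expect 0.
pool_count_mismatches <- function(utrs, seeds_unique, expected, site_types) {
  bad <- rep(FALSE, length(utrs))
  for (s in seeds_unique) {
    want <- integer(length(utrs))
    e <- expected[expected$seed == s, , drop = FALSE]
    hit <- match(e$gene_id, names(utrs))
    want[hit[!is.na(hit)]] <- e$n_sites[!is.na(hit)]
    bad <- bad | count_sites_pool(s, utrs, site_types) != want
  }
  bad
}

# Distinct seeds sharing mature positions 2-7 share their 6mer core: a
# planted window for one is then an unavoidable 7mer-A1 (and 6mer) site for
# the other, so seed-specific planting is impossible under those site types.
check_core_collisions <- function(seeds_unique, site_types) {
  if (!any(c("7mer-A1", "6mer") %in% site_types)) return(invisible())
  cores <- substr(seeds_unique, 1L, 6L)
  if (anyDuplicated(cores) > 0L)
    stop("panel contains distinct seeds sharing positions 2-7 (a common ",
         "6mer core); planted sites cannot be seed-specific when site_types ",
         "includes 7mer-A1 or 6mer. Use site_types = c(\"8mer\", \"7mer-m8\")",
         call. = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Generate a 3'UTR pool with planted seed-complementary sites
#'
#' Plants 8mer windows (reverse complement of the seed plus the A1 anchor)
#' for each (miRNA, gene) entry of \code{site_plan} at random non-overlapping
#' offsets, and rejection-samples the background so that no unplanned window
#' of any canonical site class matches any panel seed. Planted-site recovery
#' is therefore exact, intentionally cleaner than real UTRs.
#'
#' @param panel a \code{mirna_panel}.
#' @param n_genes number of genes in the pool.
#' @param utr_length UTR length in nt.
#' @param site_plan data.frame with columns \code{mirna_id}, \code{gene_id},
#'   \code{n_sites}; genes not listed get zero sites. miRNAs sharing a seed
#'   share all planted windows (their plans add up per gene).
#' @param gene_ids gene identifiers (default \code{GENE0001} ...).
#' @param site_types site classes that must be absent off-plan (and that the
#'   matching predictor run should use). Panels in which distinct seeds share
#'   mature positions 2-7 require m8-anchored types only
#'   (\code{c("8mer", "7mer-m8")}), since a planted window for one such seed
#'   is inherently a 7mer-A1/6mer site for the other.
#' @param rng_seed integer seed.
#' @param max_attempts per-gene bound on background rejection rounds.
#' @param start,end seed window in mature coordinates.
#' @return list with \code{utrs} (named character vector) and \code{truth}:
#'   \code{sites} (data.frame \code{mirna_id}, \code{gene_id}, \code{start},
#'   \code{end}, \code{site_type}) and \code{target_sets} (named list of the
#'   genes planted for each miRNA).
#' @export
gen_utr_pool <- function(panel, n_genes, utr_length = 300L,
                         site_plan = NULL,
                         gene_ids = sprintf("GENE%04d", seq_len(n_genes)),
                         site_types = c("8mer", "7mer-m8", "7mer-A1"),
                         rng_seed = NULL, max_attempts = 100L,
                         start = 2L, end = 8L) {
  stopifnot(inherits(panel, "mirna_panel"), n_genes >= 1L,
            length(gene_ids) == n_genes)
  site_types <- match.arg(site_types, SITE_TYPES, several.ok = TRUE)
  seeds <- extract_seed(panel, start = start, end = end)
  seeds_unique <- unique(unname(seeds))
  check_core_collisions(seeds_unique, site_types)
  if (is.null(site_plan))
    site_plan <- data.frame(mirna_id = character(), gene_id = character(),
                            n_sites = integer())
  stopifnot(all(c("mirna_id", "gene_id", "n_sites") %in% names(site_plan)))
  if (!all(site_plan$mirna_id %in% panel$id))
    stop("site_plan names miRNAs absent from the panel", call. = FALSE)
  if (!all(site_plan$gene_id %in% gene_ids))
    stop("site_plan names genes outside gene_ids", call. = FALSE)

  # required window count per (unique seed, gene): plans of identical-seed
  # miRNAs add up
  if (nrow(site_plan) > 0L) {
    plan_seed <- stats::aggregate(
      n_sites ~ seed + gene_id,
      data = transform(site_plan, seed = unname(seeds[site_plan$mirna_id])),
      FUN = sum)
  } else {
    plan_seed <- data.frame(seed = character(), gene_id = character(),
                            n_sites = integer())
  }

  with_rng_seed(rng_seed, {
    utrs <- stats::setNames(rep(NA_character_, n_genes), gene_ids)
    window_truth <- list()
    pending <- gene_ids
    for (round in seq_len(max_attempts)) {
      for (g in pending) {
        pg <- plan_seed[plan_seed$gene_id == g, , drop = FALSE]
        labels <- rep(pg$seed, pg$n_sites)
        starts <- draw_window_starts(utr_length, length(labels))
        if (length(labels) > 1L) labels <- sample(labels)
        ch <- sample(RNA_ALPHABET, utr_length, replace = TRUE)
        for (j in seq_along(starts)) {
          pat <- strsplit(planted_pattern(labels[j]), "", fixed = TRUE)[[1L]]
          ch[starts[j]:(starts[j] + 7L)] <- pat
        }
        utrs[g] <- paste(ch, collapse = "")
        window_truth[[g]] <- data.frame(
          seed = labels, gene_id = rep(g, length(labels)),
          start = starts, stringsAsFactors = FALSE)
      }
      bad <- pool_count_mismatches(utrs[pending], seeds_unique, plan_seed,
                                   site_types)
      pending <- pending[bad]
      if (length(pending) == 0L) break
    }
    if (length(pending) > 0L)
      stop("background rejection failed after ", max_attempts,
           " attempts for ", length(pending), " gene(s); seed density too ",
           "high — increase utr_length or reduce planted sites",
           call. = FALSE)

    wt <- do.call(rbind, c(window_truth, list(
      data.frame(seed = character(), gene_id = character(),
                 start = integer()))))
    sites <- do.call(rbind, c(lapply(panel$id, function(id) {
      w <- wt[wt$seed == seeds[[id]], , drop = FALSE]
      if (nrow(w) == 0L) return(NULL)
      data.frame(mirna_id = id, gene_id = w$gene_id, start = w$start,
                 end = w$start + 7L, site_type = "8mer",
                 stringsAsFactors = FALSE)
    }), list(data.frame(mirna_id = character(), gene_id = character(),
                        start = integer(), end = integer(),
                        site_type = character()))))
    rownames(sites) <- NULL
    target_sets <- lapply(panel$id, function(id)
      sort(unique(sites$gene_id[sites$mirna_id == id]), method = "radix"))
    names(target_sets) <- panel$id
    list(utrs = utrs,
         truth = list(sites = sites, target_sets = target_sets,
                      rng_seed = rng_seed))
  })
}

#' Random independent site plan for a panel
#'
#' Assigns each miRNA an independent random subset of genes
#' (\code{target_fraction} of the pool) with \code{sites_per_target} planted
#' sites each — the "no engineered sharing" regime in which overlap between
#' different-seed miRNAs is driven by chance alone.
#'
#' @param panel a \code{mirna_panel}.
#' @param gene_ids gene identifiers of the pool.
#' @param target_fraction fraction of genes targeted per miRNA.
#' @param sites_per_target planted sites per (miRNA, gene).
#' @param rng_seed integer seed.
#' @return data.frame \code{mirna_id}, \code{gene_id}, \code{n_sites}.
#' @export
random_site_plan <- function(panel, gene_ids, target_fraction = 0.1,
                             sites_per_target = 1L, rng_seed = NULL) {
  stopifnot(inherits(panel, "mirna_panel"),
            target_fraction >= 0, target_fraction <= 1)
  n_t <- round(length(gene_ids) * target_fraction)
  with_rng_seed(rng_seed, {
    do.call(rbind, c(lapply(panel$id, function(id) {
      g <- sample(gene_ids, n_t)
      data.frame(mirna_id = rep(id, n_t), gene_id = g,
                 n_sites = rep(as.integer(sites_per_target), n_t),
                 stringsAsFactors = FALSE)
    }), list(data.frame(mirna_id = character(), gene_id = character(),
                        n_sites = integer()))))
  })
}

#' Generate a synthetic expression experiment with planted DE genes
#'
#' Gaussian log2-scale signals emulating triplicate transfection contrasts:
#' per-gene baselines plus i.i.d. noise, with a planted fraction of genes
#' shifted in the treated group by \code{effect_size} noise standard
#' deviations in a recorded random direction.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per group (treated and control).
#' @param de_fraction fraction of genes planted as differentially expressed
#'   (count is \code{round(n_genes * de_fraction)}).
#' @param effect_size planted shift in units of \code{noise_sd}.
#' @param noise_sd within-group standard deviation.
#' @param baseline_mean,baseline_sd distribution of per-gene baseline levels.
#' @param absent_fraction fraction of planted "absent" presence calls.
#' @param rng_seed integer seed.
#' @return list with \code{matrix} (genes x samples), \code{groups}
#'   (character vector "treated"/"control"), \code{calls}
#'   (present/absent matrix) and \code{truth} (list: \code{de_genes},
#'   \code{direction} named by gene, \code{effect_size}).
#' @export
gen_expression <- function(n_genes = 5000L, n_per_group = 3L,
                           de_fraction = 0.1, effect_size = 3,
                           noise_sd = 1, baseline_mean = 7,
                           baseline_sd = 2, absent_fraction = 0,
                           rng_seed = NULL) {
  stopifnot(de_fraction >= 0, de_fraction <= 1, n_per_group >= 2L)
  n_s <- 2L * n_per_group
  gene_ids <- sprintf("GENE%05d", seq_len(n_genes))
  sample_ids <- c(sprintf("treated_%d", seq_len(n_per_group)),
                  sprintf("control_%d", seq_len(n_per_group)))
  groups <- c(rep("treated", n_per_group), rep("control", n_per_group))
  with_rng_seed(rng_seed, {
    baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    mat <- baseline + matrix(stats::rnorm(n_genes * n_s, 0, noise_sd),
                             n_genes, n_s)
    dimnames(mat) <- list(gene_ids, sample_ids)
    n_de <- round(n_genes * de_fraction)
    de_idx <- if (n_de > 0L) sort(sample.int(n_genes, n_de)) else integer(0)
    direction <- stats::setNames(sample(c(1, -1), n_de, replace = TRUE),
                                 gene_ids[de_idx])
    if (n_de > 0L)
      mat[de_idx, seq_len(n_per_group)] <-
        mat[de_idx, seq_len(n_per_group)] +
        direction * effect_size * noise_sd
    calls <- matrix("present", n_genes, n_s, dimnames = dimnames(mat))
    if (absent_fraction > 0) {
      k <- round(length(calls) * absent_fraction)
      calls[sample.int(length(calls), k)] <- "absent"
    }
    list(matrix = mat, groups = groups, calls = calls,
         truth = list(de_genes = gene_ids[de_idx], direction = direction,
                      effect_size = effect_size, rng_seed = rng_seed))
  })
}

#' Generate a two-species ortholog scenario with target-site turnover
#'
#' Builds a species-A UTR pool with planted sites, copies it as the
#' species-B orthologs, and independently disrupts each planted site in B
#' with probability \code{turnover_rate} (the 8-nt window is resampled from
#' background, destroying the site; disruptions are rejection-validated so no
#' new site of any panel seed arises). A bijective ortholog map between the
#' two gene namespaces is emitted.
#'
#' @param panel a \code{mirna_panel}.
#' @param n_genes number of orthologous gene pairs.
#' @param turnover_rate per-site probability of loss in species B, in \[0, 1\].
#' @param utr_length UTR length in nt.
#' @param target_fraction fraction of genes carrying a site per unique seed.
#' @param site_types site classes kept clean off-plan (see [gen_utr_pool()]).
#' @param rng_seed integer seed.
#' @param max_attempts rejection bound (background and disruption sampling).
#' @return list with \code{utrs_a}, \code{utrs_b} (named character vectors in
#'   distinct namespaces \code{A_GENE...}/\code{B_GENE...}), \code{map} (an
#'   \code{ortholog_map}), \code{target_sets_a}, \code{target_sets_b} (planted
#'   truth per miRNA) and \code{truth} (data.frame per planted site:
#'   \code{seed}, \code{gene_a}, \code{gene_b}, \code{start},
#'   \code{retained}).
#' @export
gen_ortholog_scenario <- function(panel, n_genes = 500L, turnover_rate = 0,
                                  utr_length = 150L, target_fraction = 1,
                                  site_types = c("8mer", "7mer-m8", "7mer-A1"),
                                  rng_seed = NULL, max_attempts = 100L) {
  stopifnot(turnover_rate >= 0, turnover_rate <= 1)
  site_types <- match.arg(site_types, SITE_TYPES, several.ok = TRUE)
  seeds <- extract_seed(panel)
  seeds_unique <- unique(unname(seeds))
  genes_a <- sprintf("A_GENE%04d", seq_len(n_genes))
  genes_b <- sprintf("B_GENE%04d", seq_len(n_genes))
  with_rng_seed(rng_seed, {
    # one plan entry per unique seed so identical-seed miRNAs share sites
    rep_mirna <- panel$id[match(seeds_unique, unname(seeds))]
    n_t <- round(n_genes * target_fraction)
    plan <- do.call(rbind, lapply(rep_mirna, function(id) {
      data.frame(mirna_id = rep(id, n_t),
                 gene_id = sample(genes_a, n_t),
                 n_sites = rep(1L, n_t), stringsAsFactors = FALSE)
    }))
    pool_a <- gen_utr_pool(panel, n_genes, utr_length = utr_length,
                           site_plan = plan, gene_ids = genes_a,
                           site_types = site_types,
                           max_attempts = max_attempts)
    wt <- pool_a$truth$sites
    wt <- unique(data.frame(seed = unname(seeds[wt$mirna_id]),
                            gene_a = wt$gene_id, start = wt$start,
                            stringsAsFactors = FALSE))
    wt$gene_b <- genes_b[match(wt$gene_a, genes_a)]
    wt$retained <- stats::runif(nrow(wt)) >= turnover_rate

    utrs_b <- stats::setNames(pool_a$utrs, genes_b)
    pending <- unique(wt$gene_b[!wt$retained])
    kept <- wt[wt$retained, , drop = FALSE]
    if (nrow(kept) > 0L) {
      expected_b <- stats::aggregate(
        retained ~ seed + gene_id,
        data = data.frame(seed = kept$seed, gene_id = kept$gene_b,
                          retained = 1L), FUN = sum)
      names(expected_b)[3L] <- "n_sites"
    } else {
      expected_b <- data.frame(seed = character(), gene_id = character(),
                               n_sites = integer())
    }
    for (round in seq_len(max_attempts)) {
      if (length(pending) == 0L) break
      for (g in pending) {
        lost <- wt[wt$gene_b == g & !wt$retained, , drop = FALSE]
        ch <- strsplit(unname(utrs_b[g]), "", fixed = TRUE)[[1L]]
        for (j in seq_len(nrow(lost)))
          ch[lost$start[j]:(lost$start[j] + 7L)] <-
            sample(RNA_ALPHABET, 8L, replace = TRUE)
        utrs_b[g] <- paste(ch, collapse = "")
      }
      bad <- pool_count_mismatches(utrs_b[pending], seeds_unique, expected_b,
                                   site_types)
      pending <- pending[bad]
    }
    if (length(pending) > 0L)
      stop("site disruption rejection failed after ", max_attempts,
           " attempts; increase utr_length", call. = FALSE)

    target_sets_a <- lapply(panel$id, function(id) {
      sort(unique(wt$gene_a[wt$seed == seeds[[id]]]), method = "radix")
    })
    names(target_sets_a) <- panel$id
    target_sets_b <- lapply(panel$id, function(id) {
      sort(unique(wt$gene_b[wt$seed == seeds[[id]] & wt$retained]),
           method = "radix")
    })
    names(target_sets_b) <- panel$id
    list(utrs_a = pool_a$utrs, utrs_b = utrs_b,
         map = ortholog_map(genes_a, genes_b),
         target_sets_a = target_sets_a, target_sets_b = target_sets_b,
         truth = wt)
  })
}

#' Materialize a complete synthetic demo dataset on disk
#'
#' Writes a miRNA panel FASTA, a UTR pool FASTA with planted sites, an
#' expression matrix with group labels and presence calls, a probe map and an
#' ortholog scenario — every input the pipeline consumes — with all ground
#' truth recorded in the returned object.
#'
#' @param dir output directory (created if needed).
#' @param rng_seed integer seed governing every generator.
#' @return (invisibly) list of generator outputs and written file paths.
#' @export
make_fixtures <- function(dir, rng_seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- list(
    list(a = "syn-miR-001", b = "syn-miR-002", k = 0L),
    list(a = "syn-miR-001", b = "syn-miR-003", k = 1L),
    list(a = "syn-miR-001", b = "syn-miR-004", k = 5L,
         positions = c(2L, 3L, 5L, 7L, 8L))
  )
  gen <- gen_mirna_panel(6L, spec, rng_seed = rng_seed)
  pool <- gen_utr_pool(
    gen$panel, n_genes = 200L, utr_length = 240L,
    site_plan = random_site_plan(gen$panel, sprintf("GENE%04d", 1:200),
                                 target_fraction = 0.2,
                                 rng_seed = rng_seed + 1L),
    rng_seed = rng_seed + 2L)
  expr <- gen_expression(n_genes = 1000L, rng_seed = rng_seed + 3L)
  ortho <- gen_ortholog_scenario(gen$panel, n_genes = 120L,
                                 turnover_rate = 0.5, utr_length = 150L,
                                 target_fraction = 0.5,
                                 rng_seed = rng_seed + 4L)
  paths <- list(
    mirna_fasta = file.path(dir, "panel.fa"),
    utr_fasta = file.path(dir, "utrs.fa"),
    expression = file.path(dir, "expression.tsv"),
    groups = file.path(dir, "groups.tsv"),
    calls = file.path(dir, "calls.tsv"),
    probe_map = file.path(dir, "probe_map.tsv"),
    ortholog_map = file.path(dir, "orthologs.tsv"),
    utr_fasta_a = file.path(dir, "utrs_species_a.fa"),
    utr_fasta_b = file.path(dir, "utrs_species_b.fa")
  )
  write_fasta <- function(x, path) {
    Biostrings::writeXStringSet(Biostrings::BStringSet(x), path)
  }
  write_fasta(stats::setNames(gen$panel$sequence, gen$panel$id),
              paths$mirna_fasta)
  write_fasta(pool$utrs, paths$utr_fasta)
  write_tsv(data.frame(feature_id = rownames(expr$matrix), expr$matrix,
                       check.names = FALSE), paths$expression)
  write_tsv(data.frame(sample_id = colnames(expr$matrix),
                       group = expr$groups), paths$groups)
  write_tsv(data.frame(feature_id = rownames(expr$calls), expr$calls,
                       check.names = FALSE), paths$calls)
  # probe annotation: the last 10 features are unannotated; the first two
  # probes report the same gene so the SNR collapse path is exercised
  feats <- rownames(expr$matrix)
  annotated <- feats[seq_len(length(feats) - 10L)]
  symbols <- sub("GENE", "SYM", annotated)
  symbols[2L] <- symbols[1L]
  write_tsv(data.frame(probe_id = annotated, gene_symbol = symbols),
            paths$probe_map)
  write_tsv(as.data.frame(ortho$map), paths$ortholog_map)
  write_fasta(ortho$utrs_a, paths$utr_fasta_a)
  write_fasta(ortho$utrs_b, paths$utr_fasta_b)
  invisible(list(panel = gen, pool = pool, expression = expr,
                 orthologs = ortho, paths = paths))
}
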