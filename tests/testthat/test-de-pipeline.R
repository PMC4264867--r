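make_mat <- function(values, n_samples = 6, ids = NULL) {
  m <- matrix(values, ncol = n_samples, byrow = TRUE)
  rownames(m) <- ids %||% paste0("p", seq_len(nrow(m)))
  colnames(m) <- paste0("s", seq_len(n_samples))
  m
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("presence filtering removes features below half present calls", {
  mat <- make_mat(rep(1, 18), ids = c("a", "b", "c"))
  calls <- matrix("present", 3, 6, dimnames = dimnames(mat))
  calls["a", 1:4] <- "absent"   # 2/6 present -> removed
  calls["b", 1:3] <- "absent"   # 3/6 present -> kept (strict less-than rule)
  out <- presence_filter(mat, calls)
  expect_identical(rownames(out), c("b", "c"))
  # all-present matrix unchanged
  allp <- matrix("present", 3, 6, dimnames = dimnames(mat))
  expect_identical(presence_filter(mat, allp), mat)
  expect_error(presence_filter(mat, calls[, 1:3]), "shape")
})

test_that("annotation filtering drops unmapped features", {
  mat <- make_mat(rnorm(60), ids = paste0("p", 1:10))
  map <- setNames(paste0("SYM", 1:7), paste0("p", 1:7))
  expect_identical(nrow(drop_unannotated(mat, map)), 7L)
  expect_identical(drop_unannotated(mat, setNames(paste0("S", 1:10),
                                                  paste0("p", 1:10))), mat)
  expect_warning(out <- drop_unannotated(mat, setNames(character(0),
                                                       character(0))),
                 "no annotated")
  expect_identical(nrow(out), 0L)
})

test_that("SNR collapse keeps the highest mean/sd probe per gene", {
  # probe1: mean 10, sd 1 (SNR 10); probe2: mean 10, sd 4 (SNR 2.5)
  mat <- make_mat(c(9, 10, 11, 9, 10, 11,
                    6, 10, 14, 6, 10, 14,
                    5, 5, 5, 7, 7, 7),
                  ids = c("p_noisyname", "p_a", "p_single"))
  map <- c(p_noisyname = "GENE1", p_a = "GENE1", p_single = "GENE2")
  snr1 <- mean(mat[1, ]) / sd(mat[1, ])
  snr2 <- mean(mat[2, ]) / sd(mat[2, ])
  expect_gt(snr1, snr2)
  out <- snr_collapse(mat, map)
  expect_identical(rownames(out), c("GENE1", "GENE2"))
  expect_identical(unname(out["GENE1", ]), unname(mat["p_noisyname", ]))
  expect_identical(unname(out["GENE2", ]), unname(mat["p_single", ]))
  # SNR tie breaks to the lexicographically smallest probe id
  tie <- make_mat(c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1, 2, 3), ids = c("pB", "pA"))
  out_tie <- snr_collapse(tie, c(pB = "G", pA = "G"))
  expect_identical(unname(out_tie["G", ]), unname(tie["pA", ]))
  # constant probes get infinite SNR, with a warning
  const <- make_mat(c(rep(5, 6), 1, 2, 3, 1, 2, 3), ids = c("pc", "pv"))
  expect_warning(outc <- snr_collapse(const, c(pc = "G", pv = "G")),
                 "constant")
  expect_identical(unname(outc["G", ]), rep(5, 6))
  expect_error(snr_collapse(mat, map[1:2]), "annotated")
})

test_that("the SAM d statistic follows its defining formula", {
  groups <- c(rep("treated", 3), rep("control", 3))
  # treated (2,2,2), control (0,0,0): s_i = 0, with s0 = 1 -> d = 2
  mat <- make_mat(c(2, 2, 2, 0, 0, 0), ids = "g1")
  expect_identical(unname(sam_statistic(mat, groups, s0 = 1)$d), 2)
  # equal group means -> d = 0
  flat <- make_mat(c(1, 2, 3, 1, 2, 3), ids = "g1")
  expect_identical(unname(sam_statistic(flat, groups, s0 = 1)$d), 0)
  # antisymmetric under swapping the group labels
  set.seed(21)
  m <- make_mat(rnorm(30), ids = paste0("g", 1:5))
  d1 <- sam_statistic(m, groups, s0 = 0.5)$d
  d2 <- sam_statistic(m, rev(groups), s0 = 0.5)$d
  expect_equal(d1, -d2)
  # zero-variance gene with s0 = 0 is rejected with advice
  expect_error(sam_statistic(mat, groups, s0 = 0), "s0 > 0")
  # auto fudge factor is the median pooled standard error
  st <- sam_statistic(m, groups)
  expect_identical(st$s0, median(st$s))
})

test_that("permutation FDR is deterministic, monotone in delta, and calibrated", {
  ex <- gen_expression(n_genes = 400, de_fraction = 0.1, effect_size = 5,
                       rng_seed = 301)
  r1 <- permutation_fdr(ex$matrix, ex$groups, rng_seed = 1)
  r2 <- permutation_fdr(ex$matrix, ex$groups, rng_seed = 1)
  expect_identical(r1$d, r2$d)
  expect_identical(r1$significant, r2$significant)
  expect_identical(r1$n_permutations, 20L)  # all distinct 3v3 assignments
  # significant set shrinks as delta grows; infinite delta empties it
  lo <- permutation_fdr(ex$matrix, ex$groups, delta = 1)
  hi <- permutation_fdr(ex$matrix, ex$groups, delta = 2.5)
  expect_true(all(names(which(hi$significant)) %in%
                  names(which(lo$significant))))
  inf <- permutation_fdr(ex$matrix, ex$groups, delta = Inf)
  expect_identical(sum(inf$significant), 0L)
  expect_identical(inf$estimated_fdr, 0)
  # strong planted effects are recovered at the 2% FDR target
  called <- names(which(r1$significant))
  recall <- length(intersect(called, ex$truth$de_genes)) /
    length(ex$truth$de_genes)
  expect_gte(recall, 0.9)
  expect_gte(r1$estimated_fdr, 0); expect_lte(r1$estimated_fdr, 1)
})

test_that("permutation FDR rarely calls genes on null data", {
  frac <- vapply(1:5, function(s) {
    ex <- gen_expression(n_genes = 800, de_fraction = 0, rng_seed = 1000 + s)
    r <- permutation_fdr(ex$matrix, ex$groups)
    mean(r$significant)
  }, 0)
  expect_true(all(frac <= 0.05))
})

test_that("DE gene sets split by direction and overlap correctly", {
  ex <- gen_expression(n_genes = 400, de_fraction = 0.1, effect_size = 5,
                       rng_seed = 88)
  sam <- permutation_fdr(ex$matrix, ex$groups)
  sets <- de_gene_sets(sam, "demo")
  expect_identical(length(intersect(sets$up, sets$down)), 0L)
  expect_setequal(c(sets$up, sets$down), names(which(sam$significant)))
  # planted directions are respected (treated shifted by +/- effect)
  up_truth <- names(ex$truth$direction)[ex$truth$direction > 0]
  expect_true(all(sets$up %in% up_truth))
  # overlap of a result with itself is exact
  expect_identical(de_overlap(sets, sets)$cosine, 1)
  expect_identical(de_overlap(sets, sets, mode = "directional")$cosine, 1)
  # directional mode does not credit opposite-direction genes
  flip <- sets; flip$up <- sets$down; flip$down <- sets$up
  class(flip) <- "de_gene_sets"
  expect_identical(de_overlap(sets, flip, mode = "directional")$n_shared, 0L)
  expect_identical(de_overlap(sets, flip, mode = "all")$cosine, 1)
  empty <- structure(list(contrast = "x", up = character(0),
                          down = character(0), fdr_target = 0.02),
                     class = "de_gene_sets")
  expect_error(de_overlap(sets, empty), "non-empty")
})

test_that("the filter pipeline is invariant to input row order", {
  ex <- gen_expression(n_genes = 200, de_fraction = 0.1, effect_size = 4,
                       rng_seed = 55)
  map <- setNames(sub("GENE", "SYM", rownames(ex$matrix)),
                  rownames(ex$matrix))
  run <- function(mat, calls) {
    m <- presence_filter(mat, calls)
    m <- snr_collapse(drop_unannotated(m, map), map)
    permutation_fdr(m, ex$groups, rng_seed = 3)
  }
  shuffle <- sample(nrow(ex$matrix))
  r1 <- run(ex$matrix, ex$calls)
  r2 <- run(ex$matrix[shuffle, ], ex$calls[shuffle, ])
  expect_identical(r1$d, r2$d)
  expect_identical(r1$significant, r2$significant)
})

test_that("expression matrices, group labels and calls round-trip via TSV", {
  ex <- gen_expression(n_genes = 20, n_per_group = 2, rng_seed = 6,
                       absent_fraction = 0.2)
  dir <- tempfile(); dir.create(dir)
  write_tsv <- function(df, p) utils::write.table(
    df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  pm <- file.path(dir, "mat.tsv")
  write_tsv(data.frame(feature_id = rownames(ex$matrix), ex$matrix,
                       check.names = FALSE), pm)
  expect_equal(read_expression_matrix(pm), ex$matrix)
  pg <- file.path(dir, "groups.tsv")
  write_tsv(data.frame(sample_id = colnames(ex$matrix), group = ex$groups), pg)
  expect_identical(read_group_labels(pg, colnames(ex$matrix)), ex$groups)
  expect_error(read_group_labels(pg, c("nope", colnames(ex$matrix))),
               "missing sample")
  pc <- file.path(dir, "calls.tsv")
  write_tsv(data.frame(feature_id = rownames(ex$calls), ex$calls,
                       check.names = FALSE), pc)
  expect_identical(read_calls_matrix(pc), ex$calls)
})
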