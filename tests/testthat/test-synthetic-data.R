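test_that("panel generation honors mismatch constraints exactly", {
  spec <- list(
    list(a = "syn-miR-001", b = "syn-miR-002", k = 0),
    list(a = "syn-miR-001", b = "syn-miR-003", k = 1, positions = 4),
    list(a = "syn-miR-001", b = "syn-miR-004", k = 5,
         positions = c(2, 3, 5, 7, 8))
  )
  gen <- gen_mirna_panel(5, spec, rng_seed = 9)
  seeds <- extract_seed(gen$panel)
  expect_identical(gen$panel$sequence[1], gen$panel$sequence[2])  # k = 0
  expect_identical(hamming_distance(seeds[[1]], seeds[[3]]), 1L)
  expect_identical(mismatch_positions(seeds[[1]], seeds[[3]]), 4L)
  expect_identical(mismatch_positions(seeds[[1]], seeds[[4]]),
                   c(2L, 3L, 5L, 7L, 8L))
  # constrained miRNAs share non-seed regions
  nonseed <- function(s) paste0(substr(s, 1, 1), substr(s, 9, 22))
  expect_identical(nonseed(gen$panel$sequence[1]),
                   nonseed(gen$panel$sequence[4]))
  # contradictory constraints are refused
  bad <- c(spec, list(list(a = "syn-miR-002", b = "syn-miR-003", k = 5)))
  expect_error(gen_mirna_panel(5, bad, rng_seed = 9), "contradictory")
  # same seed, byte-identical output; different seed, different panel
  expect_identical(gen_mirna_panel(5, spec, rng_seed = 9)$panel, gen$panel)
  expect_false(identical(gen_mirna_panel(5, spec, rng_seed = 10)$panel,
                         gen$panel))
})

test_that("UTR pools plant exactly the requested sites and nothing else", {
  gen <- gen_mirna_panel(3, list(list(a = "syn-miR-001", b = "syn-miR-002",
                                      k = 0)), rng_seed = 4)
  genes <- sprintf("GENE%04d", 1:30)
  plan <- data.frame(mirna_id = c("syn-miR-001", "syn-miR-003", "syn-miR-003"),
                     gene_id = c("GENE0001", "GENE0001", "GENE0002"),
                     n_sites = c(3L, 1L, 2L))
  pool <- gen_utr_pool(gen$panel, 30, utr_length = 200, site_plan = plan,
                       rng_seed = 31)
  seeds <- extract_seed(gen$panel)
  # planted counts are recovered exactly by the scanner
  expect_identical(nrow(seed_match_sites(seeds[[1]], pool$utrs[["GENE0001"]])),
                   3L)
  expect_identical(nrow(seed_match_sites(seeds[[3]], pool$utrs[["GENE0001"]])),
                   1L)
  expect_identical(nrow(seed_match_sites(seeds[[3]], pool$utrs[["GENE0002"]])),
                   2L)
  # no off-target genes anywhere
  sets <- predict_targets(gen$panel, pool$utrs)
  expect_identical(sets[["syn-miR-001"]], "GENE0001")
  expect_identical(sets[["syn-miR-001"]], sets[["syn-miR-002"]])
  expect_identical(sets[["syn-miR-003"]], c("GENE0001", "GENE0002"))
  # recorded truth matches the scan
  expect_identical(pool$truth$target_sets, sets[names(sets)])
  # every truth site is an 8mer at its recorded coordinates
  for (i in seq_len(nrow(pool$truth$sites))) {
    tr <- pool$truth$sites[i, ]
    hits <- seed_match_sites(seeds[[tr$mirna_id]], pool$utrs[[tr$gene_id]])
    expect_true(any(hits$start == tr$start & hits$end == tr$end &
                    hits$site_type == "8mer"))
  }
  # empty plan -> all-empty target sets
  empty <- gen_utr_pool(gen$panel, 5, utr_length = 100, rng_seed = 3)
  expect_true(all(lengths(predict_targets(gen$panel, empty$utrs)) == 0))
  # determinism
  pool2 <- gen_utr_pool(gen$panel, 30, utr_length = 200, site_plan = plan,
                        rng_seed = 31)
  expect_identical(pool$utrs, pool2$utrs)
  # impossible density is refused with advice
  dense <- data.frame(mirna_id = "syn-miR-001", gene_id = "GENE0001",
                      n_sites = 10L)
  expect_error(gen_utr_pool(gen$panel, 30, utr_length = 40,
                            site_plan = dense, rng_seed = 1),
               "utr_length")
})

test_that("expression generator plants the stated DE fraction and directions", {
  ex <- gen_expression(n_genes = 1000, de_fraction = 0.1, rng_seed = 2)
  expect_identical(length(ex$truth$de_genes), 100L)
  expect_identical(dim(ex$matrix), c(1000L, 6L))
  expect_identical(ex$groups, c(rep("treated", 3), rep("control", 3)))
  expect_true(all(ex$calls == "present"))
  # planted genes are shifted in the recorded direction
  diff <- rowMeans(ex$matrix[, 1:3]) - rowMeans(ex$matrix[, 4:6])
  planted <- ex$truth$de_genes
  expect_gt(cor(sign(diff[planted]), ex$truth$direction[planted]), 0.95)
  # no planted genes at de_fraction 0
  expect_identical(length(gen_expression(100, de_fraction = 0,
                                         rng_seed = 1)$truth$de_genes), 0L)
  # determinism and absence planting
  expect_identical(gen_expression(50, rng_seed = 5)$matrix,
                   gen_expression(50, rng_seed = 5)$matrix)
  exa <- gen_expression(100, absent_fraction = 0.25, rng_seed = 8)
  expect_equal(mean(exa$calls == "absent"), 0.25, tolerance = 0.01)
})

test_that("null-effect simulations yield no recoverable planted genes", {
  hits <- vapply(1:5, function(s) {
    ex <- gen_expression(n_genes = 600, de_fraction = 0.1, effect_size = 0,
                         rng_seed = 900 + s)
    r <- permutation_fdr(ex$matrix, ex$groups)
    called <- names(which(r$significant))
    length(intersect(called, ex$truth$de_genes)) / length(ex$truth$de_genes)
  }, 0)
  expect_true(all(hits <= 0.05))
})

test_that("ortholog scenarios obey the turnover rate", {
  gen <- gen_mirna_panel(2, list(list(a = "syn-miR-001", b = "syn-miR-002",
                                      k = 0)), rng_seed = 21)
  sc0 <- gen_ortholog_scenario(gen$panel, n_genes = 60, turnover_rate = 0,
                               rng_seed = 1)
  expect_true(all(sc0$truth$retained))
  expect_identical(sc0$target_sets_b[["syn-miR-001"]],
                   sub("^A_", "B_", sc0$target_sets_a[["syn-miR-001"]]))
  sc1 <- gen_ortholog_scenario(gen$panel, n_genes = 60, turnover_rate = 1,
                               rng_seed = 2)
  expect_true(all(!sc1$truth$retained))
  expect_identical(lengths(sc1$target_sets_b), c("syn-miR-001" = 0L,
                                                 "syn-miR-002" = 0L))
  # retained site count is binomial around (1 - rate) * n_sites
  sc <- gen_ortholog_scenario(gen$panel, n_genes = 400, turnover_rate = 0.5,
                              rng_seed = 3)
  n <- nrow(sc$truth)
  expect_identical(n, 400L)
  expect_lt(abs(sum(sc$truth$retained) - 0.5 * n), 3 * sqrt(n * 0.25))
  # the map is bijective and covers every gene pair
  expect_identical(nrow(sc$map), 400L)
  expect_identical(anyDuplicated(sc$map$gene_a), 0L)
  expect_identical(anyDuplicated(sc$map$gene_b), 0L)
})
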