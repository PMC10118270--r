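# a syntelog_table built directly from counts (query x target)
fabricate_table <- function(counts, regions = NULL) {
  targets <- colnames(counts)
  rows <- list()
  for (t in targets)
    rows[[t]] <- data.frame(query = rownames(counts), target = t,
                            regions = if (is.null(regions)) pmax(counts[, t], 1)
                              else regions[, t],
                            syntelogs = counts[, t])
  sg <- do.call(rbind, lapply(targets, function(t) {
    q <- rownames(counts)[counts[, t] > 0]
    do.call(rbind, lapply(q, function(qq)
      data.frame(query = qq, target = t,
                 target_gene = paste0(t, "_", qq, "_", seq_len(counts[qq, t])))))
  }))
  structure(list(counts = do.call(rbind, rows), syntelog_genes = sg,
                 queries = rownames(counts), targets = targets),
            class = "syntelog_table")
}

test_that("a lossless tetraploid target yields two regions and two syntelogs everywhere", {
  sc <- evolution_scenario(n_chromosomes = 2, genes_per_chromosome = 100,
                           loss_rates_2x = c(LF = 0, MF = 0),
                           single_gene_rates = c(tandem = 0, proximal = 0,
                                                 transposed = 0, dispersed = 0),
                           addition = FALSE, seed = 7)
  ds <- simulate_dataset(sc, sequences = FALSE, expression = FALSE)
  hom <- filter_homology(dataset_homology(ds, "ref", "lineage2x"))
  bl <- chain_blocks(build_anchors(ds$ref, ds$lineages$lineage2x, hom),
                     min_span = 4, max_gap = 40)
  tab <- build_syntelog_table(ds$ref, list(lineage2x = ds$lineages$lineage2x),
                              list(lineage2x = bl))
  expect_true(all(tab$counts$regions == 2L))
  expect_true(all(tab$counts$syntelogs == 2L))
})

test_that("syntelog counts agree exactly with the truth log under loss", {
  sc <- evolution_scenario(n_chromosomes = 3, genes_per_chromosome = 150,
                           loss_rates_2x = c(LF = 0.2, MF = 0.4),
                           single_gene_rates = c(tandem = 0, proximal = 0,
                                                 transposed = 0, dispersed = 0),
                           addition = FALSE, seed = 15)
  ds <- simulate_dataset(sc, sequences = FALSE, expression = FALSE)
  hom <- filter_homology(dataset_homology(ds, "ref", "lineage2x"))
  bl <- chain_blocks(build_anchors(ds$ref, ds$lineages$lineage2x, hom),
                     min_span = 4, max_gap = 40)
  tab <- build_syntelog_table(ds$ref, list(lineage2x = ds$lineages$lineage2x),
                              list(lineage2x = bl))
  tg <- ds$truth$genes
  truth_copies <- table(tg$ancestral_id[tg$genome == "lineage2x"])
  cn <- tab$counts
  # chromosome-edge genes whose track copies were lost can fall outside the
  # block span; everywhere else both regions are detected
  expect_gte(mean(cn$regions == 2L), 0.95)
  want <- as.integer(truth_copies[cn$query])
  want[is.na(want)] <- 0L
  expect_equal(cn$syntelogs, want)
})

test_that("copy-number summary reproduces the printed C4 percentages", {
  counts <- matrix(0L, nrow = 43, ncol = 2,
                   dimnames = list(sprintf("q%02d", 1:43), c("gX", "gY")))
  counts[1:29, "gX"] <- 2L                    # 29/43 with >= 2 copies
  counts[1:6, "gY"] <- 3L                     # 6/43 with >= 3 copies
  counts[7:17, "gY"] <- 2L                    # 17/43 with >= 2 copies
  tab <- fabricate_table(counts, regions = matrix(3L, 43, 2,
                                                  dimnames = dimnames(counts)))
  s2 <- copy_number_summary(tab, rownames(counts), k = 2L)
  expect_equal(s2$pct_rounded[s2$target == "gX"], 67)
  expect_equal(s2$pct[s2$target == "gX"], 100 * 29 / 43)
  expect_equal(s2$pct_rounded[s2$target == "gY"], 40)
  s3 <- copy_number_summary(tab, rownames(counts), k = 3L)
  expect_equal(s3$pct_rounded[s3$target == "gY"], 14)
  expect_error(copy_number_summary(tab, character(0)), "empty")
})

test_that("an unambiguously enriched focal set gets the minimal p-value", {
  n <- 200
  counts <- matrix(1L, n, 2, dimnames = list(sprintf("q%03d", 1:n), c("X", "Y")))
  counts[1:10, "X"] <- 3L
  tab <- fabricate_table(counts)
  res <- permutation_retention_test(tab, sprintf("q%03d", 1:10), "X", "Y",
                                    n_perm = 500, seed = 3)
  expect_equal(res$p_raw, 0)
  expect_equal(res$p_corrected, 1 / 501)
  expect_equal(length(res$null), 500L)
})

test_that("the permutation test is deterministic and monotone in enrichment", {
  set.seed(77)
  n <- 150
  counts <- matrix(rpois(2 * n, 1.5), n, 2,
                   dimnames = list(sprintf("q%03d", 1:n), c("X", "Y")))
  tab <- fabricate_table(counts)
  focal <- sample(rownames(counts), 20)
  r1 <- permutation_retention_test(tab, focal, "X", "Y", n_perm = 300, seed = 11)
  r2 <- permutation_retention_test(tab, focal, "X", "Y", n_perm = 300, seed = 11)
  expect_identical(r1$null, r2$null)
  expect_identical(r1$p_raw, r2$p_raw)

  counts2 <- counts
  counts2[focal, "X"] <- counts2[focal, "X"] + 1L
  r3 <- permutation_retention_test(fabricate_table(counts2), focal, "X", "Y",
                                   n_perm = 300, seed = 11)
  expect_lte(r3$p_raw, r1$p_raw)
})

test_that("degenerate test inputs are rejected", {
  counts <- matrix(1L, 10, 2, dimnames = list(paste0("q", 1:10), c("X", "Y")))
  tab <- fabricate_table(counts)
  expect_error(permutation_retention_test(tab, paste0("q", 1:3), "X", "Y",
                                          n_perm = 0), "n_perm")
  expect_error(permutation_retention_test(tab, "q1", "X", "Y"), ">= 2")
  expect_error(permutation_retention_test(tab, paste0("q", 1:3), "X", "Z"),
               "targets")
})
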