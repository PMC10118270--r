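empty_blocks <- function() {
  chain_blocks(structure(data.frame(gene_a = character(), gene_b = character(),
                                    chrom_a = character(), chrom_b = character(),
                                    rank_a = integer(), rank_b = integer(),
                                    score = numeric()),
                         self_comparison = TRUE))
}

test_that("adjacency and the 10-gene window separate tandem from proximal", {
  g <- toy_genome("G", list(c1 = paste0("g", 1:30)))
  hom <- hom_table(list(c("g8", "g9"),    # ranks 7,8 -> tandem
                        c("g8", "g16"),   # distance 8 -> proximal
                        c("g8", "g19")))  # distance 11 -> not proximal
  calls <- classify_pairs(g, hom, empty_blocks(), NULL)$calls
  mode_of <- function(a, b)
    calls$mode[calls$gene_a == min(a, b) & calls$gene_b == max(a, b)]
  expect_equal(mode_of("g8", "g9"), "tandem")
  expect_equal(mode_of("g8", "g16"), "proximal")
  expect_false(mode_of("g8", "g19") %in% c("tandem", "proximal"))
})

test_that("the proximal boundary flips exactly between distance 10 and 11", {
  g <- toy_genome("G", list(c1 = paste0("g", 1:40)))
  hom <- hom_table(list(c("g1", "g11"),   # distance 10
                        c("g1", "g12")))  # distance 11
  calls <- classify_pairs(g, hom, empty_blocks(), NULL)$calls
  expect_equal(calls$mode[calls$gene_b == "g11"], "proximal")
  expect_true(calls$mode[calls$gene_b == "g12"] %in% c("transposed", "dispersed"))
})

test_that("synteny evidence outranks tandem adjacency (wgd precedence)", {
  g <- toy_genome("G", list(c1 = paste0("g", 1:10)))
  hom <- hom_table(list(c("g4", "g5")))
  # fabricate a self-synteny block containing the adjacent pair as an anchor
  blocks <- structure(list(
    blocks = data.frame(block_id = 1L, chrom_a = "c1", chrom_b = "c1",
                        orientation = "same", n_anchors = 4L,
                        start_a = 0L, end_a = 4L, start_b = 4L, end_b = 8L,
                        score = 400),
    anchors = data.frame(gene_a = c("g1", "g2", "g3", "g4"),
                         gene_b = c("g5", "g6", "g7", "g8"),
                         chrom_a = "c1", chrom_b = "c1",
                         rank_a = 0:3, rank_b = 4:7, score = 100,
                         block_id = 1L)), class = "collinear_blocks")
  # the fabricated block carries anchors absent from the homology table;
  # classify_pairs warns and keeps them as wgd, which is what is under test
  calls <- suppressWarnings(
    classify_pairs(g, hom_table(list(c("g4", "g5"), c("g4", "g8"))),
                   blocks, NULL))$calls
  expect_equal(calls$mode[calls$gene_a == "g4" & calls$gene_b == "g8"], "wgd")
  expect_equal(calls$mode[calls$gene_a == "g4" & calls$gene_b == "g5"], "tandem")
})

test_that("one-ancestral-copy pairs are transposed, others dispersed", {
  g <- toy_genome("G", list(c1 = paste0("g", 1:20), c2 = paste0("h", 1:20)))
  # outgroup synteny covers c1 genes g1..g8 (they are anchors -> ancestral)
  out <- structure(list(
    blocks = data.frame(block_id = 1L, chrom_a = "c1", chrom_b = "o1",
                        orientation = "same", n_anchors = 8L,
                        start_a = 0L, end_a = 8L, start_b = 0L, end_b = 8L,
                        score = 800),
    anchors = data.frame(gene_a = paste0("g", 1:8), gene_b = paste0("o", 1:8),
                         chrom_a = "c1", chrom_b = "o1",
                         rank_a = 0:7, rank_b = 0:7, score = 100,
                         block_id = 1L)), class = "collinear_blocks")
  hom <- hom_table(list(c("g2", "h5"),   # ancestral + non-ancestral -> transposed
                        c("h3", "h17"))) # neither ancestral -> dispersed
  calls <- classify_pairs(g, hom, empty_blocks(), out)$calls
  expect_equal(calls$mode[calls$gene_a == "g2"], "transposed")
  expect_equal(calls$mode[calls$gene_a == "h17" | calls$gene_b == "h17"], "dispersed")
})

test_that("every pair gets exactly one mode and counts re-derive from calls", {
  sc <- evolution_scenario(n_chromosomes = 3, genes_per_chromosome = 100, seed = 23)
  ds <- simulate_dataset(sc, sequences = FALSE, expression = FALSE)
  l2 <- ds$lineages$lineage2x
  hom_self <- filter_homology(dataset_homology(ds, "lineage2x"))
  hom_ref <- filter_homology(dataset_homology(ds, "ref", "lineage2x"))
  b_self <- chain_blocks(build_anchors(l2, l2, hom_self))
  b_out <- chain_blocks(build_anchors(l2, ds$ref, rbind(hom_ref, hom_self)))
  res <- classify_pairs(l2, hom_self, b_self, b_out)
  expect_false(any(duplicated(res$calls[, c("gene_a", "gene_b")])))
  expect_true(all(res$calls$mode %in% c("wgd", "tandem", "proximal",
                                        "transposed", "dispersed")))
  expect_equal(sum(res$summary$per_mode$n_pairs), nrow(res$calls))
  # independent recount
  recount <- as.vector(table(factor(res$calls$mode,
                                    c("wgd", "tandem", "proximal",
                                      "transposed", "dispersed"))))
  expect_equal(res$summary$per_mode$n_pairs, recount)
  # gene counts: each gene counted once, under its highest-precedence mode
  expect_lte(sum(res$summary$per_mode$n_genes), n_genes(l2))
})

test_that("genes without homology hits are singletons", {
  g <- toy_genome("G", list(c1 = paste0("g", 1:6)))
  res <- classify_pairs(g, hom_table(list()), empty_blocks(), NULL)
  expect_equal(res$summary$n_singletons, 6L)
  res2 <- classify_pairs(g, hom_table(list(c("g1", "g2"))), empty_blocks(), NULL)
  expect_equal(res2$summary$n_singletons, 4L)
  expect_equal(res2$summary$per_mode$n_pairs[res2$summary$per_mode$mode == "tandem"], 1L)
  expect_equal(res2$summary$per_mode$n_genes[res2$summary$per_mode$mode == "tandem"], 2L)
})
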