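test_that("collinear anchors chain into a single block; short chains are dropped", {
  a <- data.frame(gene_a = paste0("a", 1:4), gene_b = paste0("b", 1:4),
                  chrom_a = "c1", chrom_b = "d1",
                  rank_a = c(1, 2, 3, 5), rank_b = c(1, 2, 3, 4),
                  score = 50)
  bl <- chain_blocks(a, min_span = 4, max_gap = 2)
  expect_equal(nrow(bl$blocks), 1L)
  expect_equal(bl$blocks$n_anchors, 4L)
  expect_equal(bl$blocks$orientation, "same")

  bl3 <- chain_blocks(a[1:3, ], min_span = 4)
  expect_equal(nrow(bl3$blocks), 0L)
})

test_that("descending partner ranks form an inverted block", {
  a <- data.frame(gene_a = paste0("a", 1:5), gene_b = paste0("b", 1:5),
                  chrom_a = "c1", chrom_b = "d1",
                  rank_a = 1:5, rank_b = 5:1, score = 50)
  bl <- chain_blocks(a, min_span = 4)
  expect_equal(nrow(bl$blocks), 1L)
  expect_equal(bl$blocks$n_anchors, 5L)
  expect_equal(bl$blocks$orientation, "inverted")
})

test_that("anchors resolve ranks; self-comparison drops identity; unknown ids error", {
  ga <- toy_genome("A", list(c1 = paste0("a", 1:10)))
  gb <- toy_genome("B", list(d1 = paste0("b", 1:10)))
  hom <- hom_table(lapply(1:10, function(i) c(paste0("a", i), paste0("b", i))))
  an <- build_anchors(ga, gb, hom)
  expect_equal(nrow(an), 10L)
  expect_equal(an$rank_a, an$rank_b)

  expect_equal(nrow(build_anchors(ga, ga, hom_table(list(c("a1", "a1"))))), 0L)
  expect_error(build_anchors(ga, gb, hom_table(list(c("a1", "gX")))), "gX")
})

test_that("dynamic-programming chains match exhaustive enumeration", {
  set.seed(99)
  n_checked <- 0
  for (i in 1:100) {
    an <- random_anchor_instance(sample(4:12, 1))
    got <- chain_blocks(an, min_span = 2, max_gap = 25)
    want <- oracle_best_chain_score(an, max_gap = 25, gap_penalty = 1)
    if (want$len < 2) next  # optimum is a bare anchor, below any min_span
    n_checked <- n_checked + 1
    expect_gt(nrow(got$blocks), 0)
    expect_equal(max(got$blocks$score), want$score, tolerance = 1e-9)
  }
  expect_gt(n_checked, 50)
})

test_that("blocks are symmetric under genome exchange", {
  set.seed(7)
  ga <- toy_genome("A", list(c1 = paste0("a", 1:30)))
  gb <- toy_genome("B", list(d1 = paste0("b", 1:30)))
  idx <- sample(30, 20)
  hom <- hom_table(lapply(idx, function(i) c(paste0("a", i), paste0("b", i))))
  ab <- chain_blocks(build_anchors(ga, gb, hom))$blocks
  ba <- chain_blocks(build_anchors(gb, ga, hom))$blocks
  expect_equal(nrow(ab), nrow(ba))
  expect_equal(ab[, c("start_a", "end_a", "start_b", "end_b")],
               ba[, c("start_b", "end_b", "start_a", "end_a")],
               ignore_attr = TRUE)
})

test_that("depth counts block coverage and is conserved", {
  g <- toy_genome("A", list(c1 = paste0("a", 1:20)))
  blocks <- structure(list(
    blocks = data.frame(block_id = 1L, chrom_a = "c1", chrom_b = "d1",
                        orientation = "same", n_anchors = 5L,
                        start_a = 0L, end_a = 10L, start_b = 0L, end_b = 10L,
                        score = 100),
    anchors = data.frame()), class = "collinear_blocks")
  d <- compute_depth(blocks, g, "a")
  expect_equal(d$genes$depth, c(rep(1L, 10), rep(0L, 10)))
  expect_equal(sum(d$genes$depth),
               sum(blocks$blocks$end_a - blocks$blocks$start_a))
  expect_equal(d$modal_depth, 1L)
})

test_that("simulated ploidy series yields 1:2, 1:3 and an undefined empty case", {
  sc <- evolution_scenario(n_chromosomes = 2, genes_per_chromosome = 120,
                           seed = 14)
  ds <- simulate_dataset(sc, sequences = FALSE, expression = FALSE)
  for (spec in list(c("lineage2x", "1:2"), c("lineage3x", "1:3"))) {
    hom <- rbind(filter_homology(dataset_homology(ds, "ref", spec[1])),
                 filter_homology(dataset_homology(ds, spec[1])))
    bl <- chain_blocks(build_anchors(ds$ref, ds$lineages[[spec[1]]], hom))
    s <- summarize_depth_ratio(compute_depth(bl, ds$ref, "a"),
                               compute_depth(bl, ds$lineages[[spec[1]]], "b"))
    expect_equal(s$ratio_label, spec[2])
  }
  empty <- chain_blocks(data.frame(gene_a = character(), gene_b = character(),
                                   chrom_a = character(), chrom_b = character(),
                                   rank_a = integer(), rank_b = integer(),
                                   score = numeric()))
  s0 <- summarize_depth_ratio(compute_depth(empty, ds$ref, "a"),
                              compute_depth(empty, ds$ref, "a"))
  expect_true(s0$undefined)
})
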