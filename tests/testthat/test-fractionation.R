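test_that("two clean target chromosomes form two tracks labelled by retention", {
  sc <- evolution_scenario(n_chromosomes = 1, genes_per_chromosome = 100,
                           loss_rates_2x = c(LF = 0.1, MF = 0.5),
                           single_gene_rates = c(tandem = 0, proximal = 0,
                                                 transposed = 0, dispersed = 0),
                           addition = FALSE, seed = 6)
  ds <- simulate_dataset(sc, sequences = FALSE, expression = FALSE)
  hom <- filter_homology(dataset_homology(ds, "ref", "lineage2x"))
  bl <- chain_blocks(build_anchors(ds$ref, ds$lineages$lineage2x, hom))
  asg <- assign_subgenomes(ds$ref, bl, ploidy = 2L)
  expect_setequal(unique(asg$tracks$label), c("LF", "MF"))
  # the low-loss subgenome is the LF track
  lf_chrom <- unique(asg$tracks$chrom_b[asg$tracks$label == "LF"])
  expect_equal(lf_chrom, "chr01A")
})

test_that("zero loss gives 100% retention in every window", {
  sc <- evolution_scenario(n_chromosomes = 2, genes_per_chromosome = 150,
                           loss_rates_2x = c(LF = 0, MF = 0),
                           single_gene_rates = c(tandem = 0, proximal = 0,
                                                 transposed = 0, dispersed = 0),
                           addition = FALSE, seed = 3)
  ds <- simulate_dataset(sc, sequences = FALSE, expression = FALSE)
  hom <- filter_homology(dataset_homology(ds, "ref", "lineage2x"))
  bl <- chain_blocks(build_anchors(ds$ref, ds$lineages$lineage2x, hom))
  prof <- retention_windows(assign_subgenomes(ds$ref, bl, 2L))
  expect_true(all(prof$windows$retained_pct == 100))
  expect_true(all(prof$genome_wide$retained_pct_all == 100))
})

test_that("genome-wide retention recovers biased loss rates within 3 points", {
  sc <- evolution_scenario(n_chromosomes = 5, genes_per_chromosome = 200,
                           loss_rates_2x = c(LF = 0.23, MF = 0.47),
                           single_gene_rates = c(tandem = 0, proximal = 0,
                                                 transposed = 0, dispersed = 0),
                           addition = FALSE, seed = 19)
  ds <- simulate_dataset(sc, sequences = FALSE, expression = FALSE)
  hom <- filter_homology(dataset_homology(ds, "ref", "lineage2x"))
  bl <- chain_blocks(build_anchors(ds$ref, ds$lineages$lineage2x, hom))
  prof <- retention_windows(assign_subgenomes(ds$ref, bl, 2L))
  gw <- prof$genome_wide
  expect_lt(abs(gw$retained_pct_all[gw$track == "LF"] - 77), 3)
  expect_lt(abs(gw$retained_pct_all[gw$track == "MF"] - 53), 3)
})

test_that("tiling windows average to the genome-wide retention", {
  sc <- evolution_scenario(n_chromosomes = 2, genes_per_chromosome = 200,
                           addition = FALSE, seed = 10,
                           single_gene_rates = c(tandem = 0, proximal = 0,
                                                 transposed = 0, dispersed = 0))
  ds <- simulate_dataset(sc, sequences = FALSE, expression = FALSE)
  asg <- truth_assignment(ds, "lineage2x")
  prof <- retention_windows(asg, window = 100L, step = 100L)
  for (lab in asg$labels) {
    w <- prof$windows[prof$windows$track == lab, ]
    gw <- prof$genome_wide$retained_pct_all[prof$genome_wide$track == lab]
    expect_lt(abs(stats::weighted.mean(w$retained_pct, w$window_size) - gw), 0.5)
  }
})

test_that("short chromosomes yield a single truncated, flagged window", {
  sc <- evolution_scenario(n_chromosomes = 1, genes_per_chromosome = 40,
                           addition = FALSE, seed = 2,
                           single_gene_rates = c(tandem = 0, proximal = 0,
                                                 transposed = 0, dispersed = 0))
  ds <- simulate_dataset(sc, sequences = FALSE, expression = FALSE)
  prof <- retention_windows(truth_assignment(ds, "lineage2x"), window = 100L)
  expect_equal(length(unique(prof$windows$window_start_rank)), 1L)
  expect_true(all(prof$windows$truncated))
  expect_true(all(prof$windows$window_size == 40L))
})

test_that("track labels are ordered by retention by construction", {
  for (seed in c(1, 5, 9)) {
    sc <- evolution_scenario(n_chromosomes = 3, genes_per_chromosome = 120,
                             seed = seed)
    ds <- simulate_dataset(sc, sequences = FALSE, expression = FALSE)
    hom <- rbind(filter_homology(dataset_homology(ds, "ref", "lineage3x")),
                 filter_homology(dataset_homology(ds, "lineage3x")))
    bl <- chain_blocks(build_anchors(ds$ref, ds$lineages$lineage3x, hom))
    gw <- retention_windows(assign_subgenomes(ds$ref, bl, 3L))$genome_wide
    counts <- gw$n_retained[match(c("LF", "MF1", "MF2"), gw$track)]
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("the window sign test is calibrated under equal loss and powered under bias", {
  run_sign_p <- function(lf, mf, seed) {
    sc <- evolution_scenario(n_chromosomes = 5, genes_per_chromosome = 200,
                             loss_rates_2x = c(LF = lf, MF = mf),
                             single_gene_rates = c(tandem = 0, proximal = 0,
                                                   transposed = 0, dispersed = 0),
                             addition = FALSE, seed = seed)
    ds <- simulate_dataset(sc, sequences = FALSE, expression = FALSE)
    prof <- retention_windows(truth_assignment(ds, "lineage2x"))
    summarize_bias(prof)$pairwise$sign_test_p[1]
  }
  null_p <- vapply(1:50, function(s) run_sign_p(0.35, 0.35, 1000 + s), numeric(1))
  expect_gte(mean(null_p > 0.05), 0.90)
  power_p <- vapply(1:50, function(s) run_sign_p(0.2, 0.5, 2000 + s), numeric(1))
  expect_gte(mean(power_p < 0.01), 0.95)
})

test_that("bias summary requires at least two tracks", {
  prof <- structure(list(
    windows = data.frame(chrom = "c", window_start_rank = 0, window_size = 10,
                         track = "LF", truncated = FALSE, retained_pct = 80),
    genome_wide = data.frame(track = "LF", n_retained = 8, n_covered = 10,
                             retained_pct_all = 80, retained_pct_covered = 80),
    window = 100L, step = 10L), class = "retention_profile")
  expect_error(summarize_bias(prof), ">= 2 tracks")
})
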