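test_that("the ancestral genome has the requested layout and valid CDS", {
  sc <- evolution_scenario(n_chromosomes = 2, genes_per_chromosome = 50,
                           codons_per_gene = 100, seed = 5)
  anc <- simulate_ancestor(sc)
  expect_equal(n_genes(anc), 100L)
  expect_equal(as.integer(tapply(anc$genes$rank, anc$genes$chromosome, max)), c(49L, 49L))
  expect_true(all(nchar(anc$cds) == 300L))
  expect_true(all(startsWith(anc$cds, "ATG")))
  stops <- vapply(anc$cds, function(s) {
    cod <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    any(cod %in% c("TAA", "TAG", "TGA"))
  }, logical(1))
  expect_false(any(stops))
})

test_that("the simulator is byte-deterministic given the seed", {
  sc <- evolution_scenario(n_chromosomes = 2, genes_per_chromosome = 40,
                           codons_per_gene = 60, seed = 9)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(simulate_dataset(sc), d1)
  write_dataset(simulate_dataset(sc), d2)
  for (f in c("ref.gff3", "ref.cds.fasta", "lineage2x.gff3", "lineage2x.cds.fasta",
              "homology.tsv", "expression.tsv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("no loss and no single-gene duplication doubles the gene count", {
  sc <- evolution_scenario(n_chromosomes = 2, genes_per_chromosome = 50,
                           loss_rates_2x = c(LF = 0, MF = 0),
                           loss_rates_3x = c(LF = 0, MF1 = 0, MF2 = 0),
                           single_gene_rates = c(tandem = 0, proximal = 0,
                                                 transposed = 0, dispersed = 0),
                           seed = 2)
  ds <- evolve_polyploid_lineages(simulate_ancestor(sc), sc)
  expect_equal(n_genes(ds$lineages$lineage2x), 200L)
  expect_equal(n_genes(ds$lineages$lineage3x), 300L)
})

test_that("realized retention matches the binomial expectation", {
  sc <- evolution_scenario(n_chromosomes = 5, genes_per_chromosome = 200,
                           loss_rates_2x = c(LF = 0.2, MF = 0.45),
                           single_gene_rates = c(tandem = 0, proximal = 0,
                                                 transposed = 0, dispersed = 0),
                           addition = FALSE, seed = 13)
  ds <- evolve_polyploid_lineages(simulate_ancestor(sc), sc)
  ret <- ds$truth$retention
  lf <- ret$retained_fraction[ret$subgenome == "LF"]
  mf <- ret$retained_fraction[ret$subgenome == "MF"]
  expect_lt(abs(lf - 0.80), 0.03)
  expect_lt(abs(mf - 0.55), 0.03)
})

test_that("tandem copies are always rank-adjacent to their source", {
  sc <- evolution_scenario(n_chromosomes = 5, genes_per_chromosome = 200,
                           single_gene_rates = c(tandem = 0.05, proximal = 0,
                                                 transposed = 0, dispersed = 0),
                           addition = FALSE, seed = 21)
  ds <- evolve_polyploid_lineages(simulate_ancestor(sc), sc)
  tp <- ds$truth$pairs[ds$truth$pairs$event == "tandem", ]
  expect_gt(nrow(tp), 30)
  g <- ds$lineages$lineage2x
  r <- setNames(g$genes$rank, g$genes$id)
  ch <- setNames(g$genes$chromosome, g$genes$id)
  expect_true(all(ch[tp$gene_a] == ch[tp$gene_b]))
  expect_true(all(abs(r[tp$gene_a] - r[tp$gene_b]) == 1L))
})

test_that("planted proximal pairs sit at rank distance 2..10", {
  sc <- evolution_scenario(n_chromosomes = 5, genes_per_chromosome = 200,
                           single_gene_rates = c(tandem = 0, proximal = 0.05,
                                                 transposed = 0, dispersed = 0),
                           addition = FALSE, seed = 22)
  ds <- evolve_polyploid_lineages(simulate_ancestor(sc), sc)
  tp <- ds$truth$pairs[ds$truth$pairs$event == "proximal", ]
  g <- ds$lineages$lineage2x
  r <- setNames(g$genes$rank, g$genes$id)
  d <- abs(r[tp$gene_a] - r[tp$gene_b])
  # later insertions between a planted pair can stretch it slightly
  expect_true(all(d >= 2))
  expect_gte(mean(d <= 10), 0.95)
})

test_that("total loss is rejected and truth partitions every genome", {
  sc <- evolution_scenario(seed = 1)
  sc$loss_rates_2x <- c(LF = 1, MF = 1)
  expect_error(evolve_polyploid_lineages(simulate_ancestor(sc), sc), "empty")

  ds <- simulate_dataset(evolution_scenario(n_chromosomes = 3,
                                            genes_per_chromosome = 60, seed = 4),
                         sequences = FALSE, expression = FALSE)
  for (lname in names(ds$lineages)) {
    tg <- ds$truth$genes[ds$truth$genes$genome == lname, ]
    expect_setequal(tg$id, ds$lineages[[lname]]$genes$id)
    expect_false(any(duplicated(tg$id)))
  }
})

test_that("retention is non-increasing in the loss rate at fixed seed", {
  rates <- c(0.1, 0.3, 0.5, 0.8)
  got <- vapply(rates, function(rate) {
    sc <- evolution_scenario(n_chromosomes = 2, genes_per_chromosome = 150,
                             loss_rates_2x = c(LF = rate, MF = rate),
                             single_gene_rates = c(tandem = 0, proximal = 0,
                                                   transposed = 0, dispersed = 0),
                             addition = FALSE, seed = 31)
    ds <- evolve_polyploid_lineages(simulate_ancestor(sc), sc)
    mean(ds$truth$retention$retained_fraction)
  }, numeric(1))
  expect_true(all(diff(got) < 0))
})

test_that("event Ks targets separate in the simulated sequences", {
  sc <- evolution_scenario(n_chromosomes = 2, genes_per_chromosome = 150,
                           codons_per_gene = 200, wgd_ks = 0.5,
                           addition_ks = 0.25, seed = 17,
                           single_gene_rates = c(tandem = 0, proximal = 0,
                                                 transposed = 0, dispersed = 0))
  ds <- simulate_dataset(sc, expression = FALSE)
  tp <- ds$truth$pairs[ds$truth$pairs$genome == "lineage3x", ]
  cds <- ds$lineages$lineage3x$cds
  kk <- kaks_table(tp, cds)
  m_add <- mean(kk$Ks[kk$event == "addition"], na.rm = TRUE)
  m_wgd <- mean(kk$Ks[kk$event == "wgd"], na.rm = TRUE)
  expect_lt(abs(m_add - 0.25), 0.05)
  expect_lt(abs(m_wgd - 0.50), 0.05)
  expect_lt(m_add, m_wgd)
})

test_that("omega 0 yields Ka = 0 and Ks target 0 yields identical ohnologs", {
  sc <- evolution_scenario(n_chromosomes = 1, genes_per_chromosome = 40,
                           codons_per_gene = 100, omega = 0, seed = 8,
                           addition = FALSE,
                           loss_rates_2x = c(LF = 0, MF = 0),
                           single_gene_rates = c(tandem = 0, proximal = 0,
                                                 transposed = 0, dispersed = 0))
  ds <- simulate_dataset(sc, expression = FALSE)
  tp <- ds$truth$pairs[ds$truth$pairs$genome == "lineage2x", ][1:20, ]
  kk <- kaks_table(tp, ds$lineages$lineage2x$cds)
  # no nonsynonymous changes are introduced; the tiny residue comes from
  # pathway averaging over codons hit twice by synonymous changes
  expect_gt(mean(kk$Ka == 0), 0.5)
  expect_lt(mean(kk$Ka), 0.01)

  sc0 <- evolution_scenario(n_chromosomes = 1, genes_per_chromosome = 30,
                            wgd_ks = 0, addition = FALSE, seed = 8,
                            loss_rates_2x = c(LF = 0, MF = 0),
                            single_gene_rates = c(tandem = 0, proximal = 0,
                                                  transposed = 0, dispersed = 0))
  ds0 <- simulate_dataset(sc0, expression = FALSE)
  tp0 <- ds0$truth$pairs[1:10, ]
  cds0 <- ds0$lineages$lineage2x$cds
  expect_true(all(cds0[tp0$gene_a] == cds0[tp0$gene_b]))
})

test_that("expression is deterministic with subgenome-neutral null", {
  sc <- evolution_scenario(n_chromosomes = 2, genes_per_chromosome = 100,
                           dominance_effect = 1, seed = 12)
  ds <- simulate_dataset(sc, sequences = FALSE)
  ds2 <- simulate_dataset(sc, sequences = FALSE)
  expect_identical(unclass(ds$expression), unclass(ds2$expression))
  tg <- ds$truth$genes
  lf <- rowMeans(ds$expression)[tg$id[tg$genome == "lineage2x" & tg$subgenome == "LF"]]
  mf <- rowMeans(ds$expression)[tg$id[tg$genome == "lineage2x" & tg$subgenome == "MF"]]
  # log-scale means agree within sampling noise under no dominance
  expect_lt(abs(mean(log(lf)) - mean(log(mf))), 3 * sqrt(1/length(lf) + 1/length(mf)) * 1.6)
})
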