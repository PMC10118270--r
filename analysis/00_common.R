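# Shared plumbing for the numbered analysis scripts: locations, the study
# scenario, and loaders for the dataset directory written by 01_simulate.R.
library(syntevo)

data_dir <- "results/dataset"
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

study_scenario <- function(seed = 1L) evolution_scenario(seed = seed)
study_config <- function(seed = 1L) analysis_config(seed = seed)

load_genomes <- function() {
  ref <- read_cds(read_gene_models(file.path(data_dir, "ref.gff3"), name = "ref"),
                  file.path(data_dir, "ref.cds.fasta"))
  l2 <- read_cds(read_gene_models(file.path(data_dir, "lineage2x.gff3"),
                                  name = "lineage2x"),
                 file.path(data_dir, "lineage2x.cds.fasta"))
  l3 <- read_cds(read_gene_models(file.path(data_dir, "lineage3x.gff3"),
                                  name = "lineage3x"),
                 file.path(data_dir, "lineage3x.cds.fasta"))
  list(ref = ref, l2 = l2, l3 = l3)
}

load_hom <- function() read_homology(file.path(data_dir, "homology.tsv"))

# the dataset's homology table spans all three genomes; keep only the pairs
# whose genes are known to the two genomes being compared (within-genome
# pairs ride along so tandem-array collapse can see them)
hom_for <- function(hom, ...) {
  ids <- unlist(lapply(list(...), function(g) g$genes$id))
  hom[hom$gene_a %in% ids & hom$gene_b %in% ids, , drop = FALSE]
}

chain_pair <- function(a, b, hom, cfg = study_config(),
                       min_span = cfg$min_span, max_gap = cfg$max_gap)
  chain_blocks(build_anchors(a, b, hom_for(hom, a, b)), min_span = min_span,
               max_gap = max_gap, gap_penalty = cfg$gap_penalty)
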