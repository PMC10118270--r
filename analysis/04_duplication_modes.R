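#!/usr/bin/env Rscript
# Stage 4: classify duplicate gene pairs of each polyploid lineage into
# WGD / tandem / proximal / transposed / dispersed modes, using self-synteny
# for ohnolog evidence and the 1x reference as the synteny outgroup for
# ancestral-locus calls.
source("analysis/00_common.R")

g <- load_genomes()
hom <- load_hom()

for (spec in list(list(g$l2, "lineage2x"), list(g$l3, "lineage3x"))) {
  genome <- spec[[1]]
  b_self <- chain_pair(genome, genome, hom)
  b_out <- chain_pair(genome, g$ref, hom)
  calls <- classify_pairs(genome, hom_for(hom, genome), b_self, b_out)
  write_duplication_calls(calls,
                          file.path(out_dir, paste0("duplication_", spec[[2]], ".tsv")))
  cat("==", spec[[2]], "\n")
  print(calls$summary)
}
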