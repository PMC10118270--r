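#!/usr/bin/env Rscript
# Stage 2: collinear-block detection and syntenic depth. The three pairwise
# genome comparisons should read 1:2, 1:3 and 2:3 genome equivalents - the
# ploidy fingerprint of one shared WGD plus one genome addition.
source("analysis/00_common.R")

g <- load_genomes()
hom <- load_hom()

ratios <- list()
for (cmp in list(c("ref", "l2", "ref_vs_2x"), c("ref", "l3", "ref_vs_3x"),
                 c("l2", "l3", "x2_vs_x3"))) {
  bl <- chain_pair(g[[cmp[1]]], g[[cmp[2]]], hom)
  write_blocks(bl, file.path(out_dir, paste0("blocks_", cmp[3], ".tsv")))
  s <- summarize_depth_ratio(compute_depth(bl, g[[cmp[1]]], "a"),
                             compute_depth(bl, g[[cmp[2]]], "b"))
  ratios[[cmp[3]]] <- s$ratio_label
  cat(sprintf("%-10s depth ratio %s\n", cmp[3], s$ratio_label))
  pct <- rbind(side_a = round(as.vector(s$pct_a), 1),
               side_b = round(as.vector(s$pct_b), 1))
  colnames(pct) <- paste0("depth", 0:6)
  print(pct)
}
writeLines(jsonlite::toJSON(ratios, auto_unbox = TRUE),
           file.path(out_dir, "depth_ratios.json"))
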