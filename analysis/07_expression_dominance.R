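#!/usr/bin/env Rscript
# Stage 7: ohnolog expression dominance ("horserace"). Syntenic ohnolog
# pairs (2x) and triads (3x) are derived from the subgenome assignment, and
# per sample the replicate TPMs of each group are compared by equal-variance
# two-sided t-tests at P <= 0.05, n = 3.
source("analysis/00_common.R")

g <- load_genomes()
hom <- load_hom()
cfg <- study_config()
expr <- read_expression(file.path(data_dir, "expression.tsv"))

for (spec in list(list(g$l2, 2L, "lineage2x"), list(g$l3, 3L, "lineage3x"))) {
  bl <- chain_pair(g$ref, spec[[1]], hom)
  asg <- assign_subgenomes(g$ref, bl, ploidy = spec[[2]])
  groups <- ohnolog_groups_from_assignment(asg, bl)
  calls <- dominance_calls(groups, expr, alpha = cfg$alpha,
                           triad_rule = cfg$triad_rule)
  s <- summarize_dominance(calls)
  utils::write.table(s, file.path(out_dir, paste0("dominance_", spec[[3]], ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat("==", spec[[3]], ":", nrow(groups), "syntenic ohnolog groups\n")
  print(s, row.names = FALSE)
}
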