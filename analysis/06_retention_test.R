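#!/usr/bin/env Rscript
# Stage 6: per-query syntelog counting across both polyploid targets and
# the permutation test for preferential retention of a focal gene family
# (emulating the C4 pathway set: genes kept in duplicate by the 2x lineage).
source("analysis/00_common.R")

g <- load_genomes()
hom <- load_hom()
cfg <- study_config()

synchain <- function(a, b) chain_pair(a, b, hom, min_span = cfg$synfind_min_span,
                                      max_gap = cfg$synfind_max_gap)
tab <- build_syntelog_table(g$ref,
                            list(lineage2x = g$l2, lineage3x = g$l3),
                            list(lineage2x = synchain(g$ref, g$l2),
                                 lineage3x = synchain(g$ref, g$l3)))
write_syntelog_table(tab, file.path(out_dir, "syntelog_table.tsv"))

mat <- syntevo:::syntelog_matrix(tab)
set.seed(cfg$seed)
focal <- sample(rownames(mat)[mat[, "lineage2x"] >= 2], 43)
cn <- rbind(copy_number_summary(tab, focal, k = 2L),
            copy_number_summary(tab, focal, k = 3L))
print(cn, row.names = FALSE)

res <- permutation_retention_test(tab, focal, "lineage2x", "lineage3x",
                                  n_perm = cfg$n_perm, seed = cfg$seed)
print(res)
jsonlite::write_json(unclass(res), file.path(out_dir, "retention_test.json"),
                     auto_unbox = TRUE, digits = NA)
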