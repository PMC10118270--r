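#!/usr/bin/env Rscript
# Stage 1: simulate the study system - a 1x reference genome plus a
# tetraploid-derived (2x) and a hexaploid-derived (3x) lineage evolved from
# a common ancestor through a shared WGD, a later genome addition, biased
# fractionation, single-gene duplications, codon divergence and
# subgenome-biased expression - and write it as standard-format files with
# the truth log.
source("analysis/00_common.R")

scenario <- study_scenario()
ds <- simulate_dataset(scenario)
write_dataset(ds, data_dir)

cat("Simulated dataset written to", data_dir, "\n")
cat(sprintf("  reference: %d genes; 2x lineage: %d; 3x lineage: %d\n",
            n_genes(ds$ref), n_genes(ds$lineages$lineage2x),
            n_genes(ds$lineages$lineage3x)))
print(ds$truth$retention, row.names = FALSE)
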