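#!/usr/bin/env Rscript
# Stage 5: molecular dating. NG86 Ka/Ks on every WGD-mode (ohnolog) pair,
# then Gaussian-mixture decomposition of the Ks distribution (Ks <= 4) to
# locate the polyploidy peaks: the 2x lineage carries one peak (the shared
# WGD), the 3x lineage two (genome addition, younger; shared WGD, older).
source("analysis/00_common.R")

g <- load_genomes()
cfg <- study_config()

for (spec in list(list(g$l2, "lineage2x", c("shared-WGD")),
                  list(g$l3, "lineage3x", c("genome-addition", "shared-WGD")))) {
  calls <- utils::read.table(file.path(out_dir, paste0("duplication_", spec[[2]], ".tsv")),
                             header = TRUE, sep = "\t")
  wgd <- calls[calls$mode == "wgd", c("gene_a", "gene_b")]
  kk <- kaks_table(wgd, spec[[1]]$cds)
  utils::write.table(kk, file.path(out_dir, paste0("kaks_", spec[[2]], ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fit <- assign_ks_peaks(fit_ks_mixture(kk$Ks[!is.na(kk$Ks)], ks_max = cfg$ks_max),
                         spec[[3]])
  jsonlite::write_json(unclass(fit),
                       file.path(out_dir, paste0("ks_fit_", spec[[2]], ".json")),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  cat("==", spec[[2]], ":", nrow(kk), "ohnolog pairs\n")
  print(fit)
  cat("median Ka/Ks:", round(stats::median(kk$omega, na.rm = TRUE), 3), "\n")
}
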