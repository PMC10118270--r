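#' Classify duplicate gene pairs by mode
#'
#' Follows the standard five-mode hierarchy with fixed precedence
#' wgd > tandem > proximal > transposed > dispersed:
#' pairs that are anchors in self-synteny blocks are WGD (ohnolog) pairs;
#' remaining same-chromosome pairs at rank distance 1 are tandem; at rank
#' distance 2..10 proximal; remaining pairs where exactly one member sits at
#' an ancestral locus are transposed; everything else is dispersed. A gene's
#' ancestral-locus status is membership in any self-synteny anchor or any
#' genome-vs-outgroup anchor. Genes without any homology hit are singletons.
#'
#' @param genome the target `genome`.
#' @param homology filtered within-genome homology pairs.
#' @param self_blocks `collinear_blocks` from the genome's self-comparison.
#' @param outgroup_blocks `collinear_blocks` from the genome-vs-outgroup
#'   comparison (genome on side "a"); may be `NULL`.
#' @return object of class `duplication_calls`: list with `calls`
#'   (gene_a, gene_b, mode, evidence), `singletons`, and `summary` (a
#'   `mode_summary`, see [summarize_modes()]).
#' @export
classify_pairs <- function(genome, homology, self_blocks, outgroup_blocks = NULL) {
  ids <- genome$genes$id
  r <- gene_ranks(genome); ch <- gene_chromosomes(genome)
  hom <- homology[homology$gene_a %in% ids & homology$gene_b %in% ids, , drop = FALSE]
  hom <- hom[hom$gene_a != hom$gene_b, , drop = FALSE]
  a <- pmin(hom$gene_a, hom$gene_b); b <- pmax(hom$gene_a, hom$gene_b)
  hom <- data.frame(gene_a = a, gene_b = b)
  hom <- hom[!duplicated(hom), , drop = FALSE]

  anch <- self_blocks$anchors[!is.na(self_blocks$anchors$block_id), , drop = FALSE]
  wgd_key <- paste(pmin(anch$gene_a, anch$gene_b), pmax(anch$gene_a, anch$gene_b))
  wgd_block <- stats::setNames(anch$block_id, wgd_key)
  ancestral <- unique(c(anch$gene_a, anch$gene_b))
  if (!is.null(outgroup_blocks)) {
    oanch <- outgroup_blocks$anchors[!is.na(outgroup_blocks$anchors$block_id), ,
                                     drop = FALSE]
    ancestral <- unique(c(ancestral, oanch$gene_a[oanch$gene_a %in% ids],
                          oanch$gene_b[oanch$gene_b %in% ids]))
  }

  # synteny outranks the hit list: an anchored pair missing from the
  # homology table is kept as a WGD pair (with a warning)
  anch_a <- pmin(anch$gene_a, anch$gene_b)
  anch_b <- pmax(anch$gene_a, anch$gene_b)
  miss <- !duplicated(wgd_key) & !(wgd_key %in% paste(hom$gene_a, hom$gene_b))
  if (any(miss)) {
    warning(sum(miss), " syntenic anchor pair(s) absent from the homology table; ",
            "kept as wgd", call. = FALSE)
    hom <- rbind(hom, data.frame(gene_a = anch_a[miss], gene_b = anch_b[miss]))
  }

  key <- paste(hom$gene_a, hom$gene_b)
  is_wgd <- key %in% wgd_key
  same_chrom <- ch[hom$gene_a] == ch[hom$gene_b]
  dist <- abs(r[hom$gene_a] - r[hom$gene_b])
  is_tandem <- !is_wgd & same_chrom & dist == 1L
  is_proximal <- !is_wgd & !is_tandem & same_chrom & dist >= 2L & dist <= 10L
  anc_count <- (hom$gene_a %in% ancestral) + (hom$gene_b %in% ancestral)
  is_transposed <- !is_wgd & !is_tandem & !is_proximal & anc_count == 1L
  mode <- rep("dispersed", nrow(hom))
  mode[is_transposed] <- "transposed"
  mode[is_proximal] <- "proximal"
  mode[is_tandem] <- "tandem"
  mode[is_wgd] <- "wgd"
  evidence <- character(nrow(hom))
  evidence[is_wgd] <- paste0("block:", wgd_block[key[is_wgd]])
  evidence[is_tandem | is_proximal] <- paste0("rank_dist:", dist[is_tandem | is_proximal])
  evidence[is_transposed] <- ifelse(hom$gene_a[is_transposed] %in% ancestral,
                                    paste0("ancestral:", hom$gene_a[is_transposed]),
                                    paste0("ancestral:", hom$gene_b[is_transposed]))
  evidence[mode == "dispersed"] <- paste0("ancestral_count:", anc_count[mode == "dispersed"])

  calls <- data.frame(gene_a = hom$gene_a, gene_b = hom$gene_b,
                      mode = mode, evidence = evidence)
  singletons <- setdiff(ids, unique(c(hom$gene_a, hom$gene_b)))
  res <- structure(list(calls = calls, singletons = singletons), class = "duplication_calls")
  res$summary <- summarize_modes(res, genome)
  res
}

#' @export
print.duplication_calls <- function(x, ...) {
  cat("<duplication_calls>", nrow(x$calls), "pairs,",
      length(x$singletons), "singletons\n")
  print(x$summary$per_mode, row.names = FALSE)
  invisible(x)
}

.dup_modes <- c("wgd", "tandem", "proximal", "transposed", "dispersed")

#' Summarize duplication calls
#'
#' Per-mode pair and gene counts (a gene participating in pairs of several
#' modes is counted under its highest-precedence mode), singleton count, and
#' a per-chromosome density table.
#'
#' @param calls a `duplication_calls` object.
#' @param genome the classified `genome`.
#' @return object of class `mode_summary`: list with `per_mode` (mode,
#'   n_pairs, n_genes), `n_singletons`, `per_chromosome`.
#' @export
summarize_modes <- function(calls, genome) {
  cl <- calls$calls
  per_mode <- data.frame(mode = .dup_modes,
                         n_pairs = vapply(.dup_modes, function(m)
                           sum(cl$mode == m), integer(1)))
  gene_mode <- data.frame(gene = c(cl$gene_a, cl$gene_b), mode = rep(cl$mode, 2))
  gene_mode$prec <- match(gene_mode$mode, .dup_modes)
  gene_mode <- gene_mode[order(gene_mode$gene, gene_mode$prec), , drop = FALSE]
  gene_mode <- gene_mode[!duplicated(gene_mode$gene), , drop = FALSE]
  per_mode$n_genes <- vapply(.dup_modes, function(m)
    sum(gene_mode$mode == m), integer(1))
  ch <- gene_chromosomes(genome)
  per_chrom <- as.data.frame(table(chromosome = ch[gene_mode$gene],
                                   mode = gene_mode$mode),
                             responseName = "n_genes")
  structure(list(per_mode = per_mode,
                 n_singletons = length(calls$singletons),
                 per_chromosome = per_chrom),
            class = "mode_summary")
}

#' @export
print.mode_summary <- function(x, ...) {
  print(x$per_mode, row.names = FALSE)
  cat("singletons:", x$n_singletons, "\n")
  invisible(x)
}

#' Write duplication calls to TSV
#' @param calls a `duplication_calls` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_duplication_calls <- function(calls, path) {
  utils::write.table(calls$calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
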