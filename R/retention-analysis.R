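#' Per-query syntelog and syntenic-region counts
#'
#' For each reference query gene and each target genome, every collinear
#' block covering the query's rank contributes one syntenic region; the
#' region contributes a syntelog only if one of its anchors pairs the query
#' gene itself (otherwise the region is a "proxy": detected but fractionated
#' or translocated). Queries with zero regions in every target are excluded
#' from the table, mirroring the per-panel exclusion of genes with no
#' syntenic context.
#'
#' @param reference the query reference `genome`.
#' @param targets named list of target `genome`s.
#' @param blocks_per_target named list (same names) of `collinear_blocks`
#'   from reference-vs-target comparisons (reference on side "a").
#' @return object of class `syntelog_table`: list with `counts` (query,
#'   target, regions, syntelogs), `syntelog_genes` (query, target,
#'   target_gene), `queries`, `targets`.
#' @export
build_syntelog_table <- function(reference, targets, blocks_per_target) {
  stopifnot(identical(sort(names(targets)), sort(names(blocks_per_target))))
  g <- reference$genes
  counts <- list()
  syn_genes <- list()
  for (tname in names(targets)) {
    blocks <- blocks_per_target[[tname]]
    b <- blocks$blocks
    anch <- blocks$anchors[!is.na(blocks$anchors$block_id), , drop = FALSE]
    regions <- integer(nrow(g))
    syntelogs <- integer(nrow(g))
    for (k in seq_len(nrow(b))) {
      hit <- g$chromosome == b$chrom_a[k] & g$rank >= b$start_a[k] & g$rank < b$end_a[k]
      regions[hit] <- regions[hit] + 1L
      ba <- anch[anch$block_id == b$block_id[k], , drop = FALSE]
      with_anchor <- hit & g$id %in% ba$gene_a
      syntelogs[with_anchor] <- syntelogs[with_anchor] + 1L
      if (nrow(ba) > 0)
        syn_genes[[length(syn_genes) + 1L]] <- data.frame(
          query = ba$gene_a, target = tname, target_gene = ba$gene_b)
    }
    counts[[tname]] <- data.frame(query = g$id, target = tname,
                                  regions = regions, syntelogs = syntelogs)
  }
  counts <- do.call(rbind, counts)
  # exclusion rule: drop queries with no syntenic region in any target
  totals <- tapply(counts$regions, counts$query, sum)
  keep <- names(totals)[totals > 0]
  counts <- counts[counts$query %in% keep, , drop = FALSE]
  rownames(counts) <- NULL
  syn_genes <- if (length(syn_genes) > 0) {
    sg <- do.call(rbind, syn_genes)
    sg <- sg[sg$query %in% keep, , drop = FALSE]
    sg[!duplicated(sg), , drop = FALSE]
  } else data.frame(query = character(), target = character(),
                    target_gene = character())
  structure(list(counts = counts, syntelog_genes = syn_genes,
                 queries = sort(unique(counts$query)), targets = names(targets)),
            class = "syntelog_table")
}

#' @export
print.syntelog_table <- function(x, ...) {
  cat("<syntelog_table>", length(x$queries), "queries x",
      length(x$targets), "targets\n")
  invisible(x)
}

# queries x targets matrix of syntelog counts
syntelog_matrix <- function(table, what = c("syntelogs", "regions")) {
  what <- match.arg(what)
  m <- tapply(table$counts[[what]],
              list(table$counts$query, table$counts$target), sum)
  m[is.na(m)] <- 0
  m
}

#' Copy-number summary for a focal gene set
#'
#' Percentage of set genes retaining at least `k` syntenic copies
#' (syntelogs) in each target genome, plus the nonredundant count of
#' distinct target-genome copies contributed by the qualifying genes.
#'
#' @param table a `syntelog_table`.
#' @param gene_set reference query gene ids.
#' @param k minimum syntelog count (default 2: "expanded" copies).
#' @return data.frame per target: `n_set`, `n_at_least_k`, `pct` (exact),
#'   `pct_rounded`, `nonredundant_copies`.
#' @export
copy_number_summary <- function(table, gene_set, k = 2L) {
  if (length(gene_set) == 0) stop("empty gene set", call. = FALSE)
  absent <- setdiff(gene_set, table$queries)
  if (length(absent) > 0) {
    warning(length(absent), " set gene(s) absent from the syntelog table, excluded: ",
            paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
    gene_set <- intersect(gene_set, table$queries)
  }
  if (length(gene_set) == 0) stop("no set genes present in the table", call. = FALSE)
  cn <- table$counts
  sg <- table$syntelog_genes
  out <- lapply(table$targets, function(tname) {
    sel <- cn[cn$target == tname & cn$query %in% gene_set, , drop = FALSE]
    qual <- sel$query[sel$syntelogs >= k]
    copies <- unique(sg$target_gene[sg$target == tname & sg$query %in% qual])
    data.frame(target = tname, n_set = length(gene_set),
               n_at_least_k = length(qual),
               pct = 100 * length(qual) / length(gene_set),
               pct_rounded = round(100 * length(qual) / length(gene_set)),
               nonredundant_copies = length(copies))
  })
  do.call(rbind, out)
}

#' Permutation test for preferential gene-set retention
#'
#' Observed statistic: mean syntelog count of the focal genes in genome X
#' divided by the mean in genome Y (or the difference of means). The null
#' distribution is the same statistic over `n_perm` random query sets of the
#' focal size, drawn uniformly without replacement within each draw from all
#' table queries. One-sided p: fraction of null draws at least as large as
#' the observation, reported both raw and with the (r+1)/(n+1) correction.
#'
#' @param table a `syntelog_table`.
#' @param focal_set focal reference gene ids (all must be table queries).
#' @param genome_x,genome_y target genome names; the claim tested is
#'   enrichment in X relative to Y.
#' @param n_perm number of null draws (default 1000).
#' @param seed integer seed; the test is fully deterministic given it.
#' @param statistic `"mean_ratio"` (default) or `"mean_diff"`.
#' @return object of class `retention_test`: list with `observed`, `null`
#'   (length `n_perm`), `p_raw`, `p_corrected`, `m`, `n_perm`, `seed`,
#'   `statistic`, `n_infinite` (null draws with zero mean in Y under the
#'   ratio statistic, scored as +Inf).
#' @export
permutation_retention_test <- function(table, focal_set, genome_x, genome_y,
                                       n_perm = 1000L, seed = 1L,
                                       statistic = c("mean_ratio", "mean_diff")) {
  statistic <- match.arg(statistic)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (!all(c(genome_x, genome_y) %in% table$targets))
    stop("genome_x/genome_y must be targets of the table", call. = FALSE)
  m <- length(focal_set)
  if (m < 2) stop("focal set must have >= 2 genes", call. = FALSE)
  mat <- syntelog_matrix(table)
  if (m > nrow(mat)) stop("focal set larger than the table", call. = FALSE)
  absent <- setdiff(focal_set, rownames(mat))
  if (length(absent) > 0)
    stop("focal gene(s) absent from table: ",
         paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  x <- mat[, genome_x]
  y <- mat[, genome_y]
  stat <- function(idx) {
    mx <- mean(x[idx]); my <- mean(y[idx])
    if (statistic == "mean_diff") return(mx - my)
    if (my == 0) return(Inf)
    mx / my
  }
  observed <- stat(match(focal_set, rownames(mat)))
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i)
    stat(sample.int(nrow(mat), m)), numeric(1))
  r <- sum(null >= observed)
  structure(list(observed = observed, null = null,
                 p_raw = r / n_perm, p_corrected = (r + 1) / (n_perm + 1),
                 m = m, n_perm = n_perm, seed = seed, statistic = statistic,
                 n_infinite = sum(is.infinite(null))),
            class = "retention_test")
}

#' @export
print.retention_test <- function(x, ...) {
  cat(sprintf("<retention_test> %s observed = %.4g; p = %.4g (corrected %.4g; %d draws)\n",
              x$statistic, x$observed, x$p_raw, x$p_corrected, x$n_perm))
  invisible(x)
}

#' Write a syntelog table to TSV
#' @param table a `syntelog_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_syntelog_table <- function(table, path) {
  utils::write.table(table$counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
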