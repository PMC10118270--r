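#' Construct a genome object
#'
#' A genome is an ordered collection of gene models grouped by chromosome,
#' optionally carrying in-frame coding sequences. All synteny computations in
#' the package operate on the dense per-chromosome gene-order index (`rank`,
#' 0-based); base-pair coordinates (1-based inclusive, as in GFF3) are kept
#' only for reporting.
#'
#' @param name genome name.
#' @param genes data.frame with columns `id`, `chromosome`, `start`, `end`,
#'   `strand`; rows are re-sorted by (chromosome, start) and ranks assigned.
#' @param cds optional named character vector of coding sequences, names are
#'   gene ids; each must be in frame (length divisible by 3).
#' @return an object of class `genome`.
#' @export
new_genome <- function(name, genes, cds = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  req <- c("id", "chromosome", "start", "end", "strand")
  missing_cols <- setdiff(req, names(genes))
  if (length(missing_cols) > 0)
    stop("genes table lacks columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  genes <- genes[, req]
  genes$id <- as.character(genes$id)
  genes$chromosome <- as.character(genes$chromosome)
  dup <- genes$id[duplicated(genes$id)]
  if (length(dup) > 0)
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  if (nrow(genes) == 0) stop("genome '", name, "' has no genes", call. = FALSE)
  if (any(genes$start > genes$end)) stop("gene with start > end", call. = FALSE)
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'", call. = FALSE)
  genes <- genes[order(genes$chromosome, genes$start, genes$id), , drop = FALSE]
  # rows are grouped by chromosome after the sort, so a running within-group
  # counter is the dense 0-based order rank
  genes$rank <- as.integer(stats::ave(seq_len(nrow(genes)), genes$chromosome,
                                      FUN = seq_along) - 1L)
  rownames(genes) <- NULL
  if (!is.null(cds)) {
    cds <- vapply(cds, toupper, character(1))
    unknown <- setdiff(names(cds), genes$id)
    if (length(unknown) > 0)
      stop("cds for unknown gene id(s): ", paste(utils::head(unknown, 5), collapse = ", "),
           call. = FALSE)
    bad <- names(cds)[nchar(cds) %% 3L != 0L]
    if (length(bad) > 0)
      stop("cds not in frame for: ", paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, genes = genes, cds = cds), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome>", x$name, "-", nrow(x$genes), "genes on",
      length(unique(x$genes$chromosome)), "chromosomes")
  if (!is.null(x$cds)) cat(";", length(x$cds), "CDS")
  cat("\n")
  invisible(x)
}

#' Number of genes in a genome
#' @param genome a `genome` object.
#' @return integer gene count.
#' @export
n_genes <- function(genome) nrow(genome$genes)

# rank lookup: named integer vector id -> rank, and id -> chromosome
gene_ranks <- function(genome) {
  stats::setNames(genome$genes$rank, genome$genes$id)
}
gene_chromosomes <- function(genome) {
  stats::setNames(genome$genes$chromosome, genome$genes$id)
}

#' Read gene models from a GFF3 file
#'
#' Features of `feature_type` are read, sorted by (chromosome, start) and
#' assigned dense 0-based ranks along each chromosome. Coordinates stay
#' 1-based inclusive as in the file.
#'
#' @param path GFF3 file.
#' @param feature_type feature type to keep (default `"gene"`).
#' @param name genome name; defaults to the file name without extension.
#' @return a `genome` object (without CDS; see [read_cds()]).
#' @export
read_gene_models <- function(path, feature_type = "gene",
                             name = sub("\\.gff3?(\\.gz)?$", "", basename(path))) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == feature_type]
  if (length(gr) == 0)
    stop("no '", feature_type, "' features in ", path, call. = FALSE)
  ids <- as.character(gr$ID)
  if (anyNA(ids) || any(ids == ""))
    stop("feature without ID attribute in ", path, call. = FALSE)
  genes <- data.frame(
    id = ids,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+")
  )
  new_genome(name, genes)
}

#' Write gene models to GFF3
#'
#' @param genome a `genome` object.
#' @param path output file.
#' @param feature_type feature type to write.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genome, path, feature_type = "gene") {
  g <- genome$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$chromosome,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand
  )
  gr$type <- feature_type
  gr$source <- "syntevo"
  gr$ID <- g$id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Attach coding sequences from a FASTA file
#' @param genome a `genome` object.
#' @param path FASTA file, one record per gene id.
#' @return the genome with `cds` filled.
#' @export
read_cds <- function(genome, path) {
  seqs <- Biostrings::readDNAStringSet(path)
  cds <- stats::setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  new_genome(genome$name, genome$genes, cds = cds)
}

#' Write coding sequences to FASTA
#' @param genome a `genome` object with CDS.
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
write_cds <- function(genome, path) {
  if (is.null(genome$cds)) stop("genome has no CDS", call. = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$cds), path, width = 70L)
  invisible(path)
}

#' Read and filter a pairwise homology table
#'
#' Reads a 4-column TSV (`gene_a`, `gene_b`, `evalue`, `bitscore`) and applies
#' the standard homolog-search filter: self-hits removed, hits above the
#' e-value cutoff removed, and per query gene only the `top_n` best-e-value
#' partners kept (ties broken by higher bitscore, then lexicographic partner
#' id), then pairs deduplicated as unordered. A pair survives only if it is
#' in the trimmed partner list of both of its genes, which makes the filter
#' idempotent.
#'
#' @param path TSV file without header.
#' @param max_evalue e-value cutoff (default `1e-10`).
#' @param top_n partners kept per query (default 5).
#' @return data.frame `gene_a`, `gene_b`, `evalue`, `bitscore`.
#' @export
read_homology <- function(path, max_evalue = 1e-10, top_n = 5L) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 4L))
    stop("malformed homology row at line ", which(nfield != 4L)[1], call. = FALSE)
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  hom <- data.frame(gene_a = m[, 1], gene_b = m[, 2],
                    evalue = suppressWarnings(as.numeric(m[, 3])),
                    bitscore = suppressWarnings(as.numeric(m[, 4])))
  bad <- which(is.na(hom$evalue) | is.na(hom$bitscore) | hom$evalue < 0)
  if (length(bad) > 0)
    stop("malformed homology row at line ", bad[1], call. = FALSE)
  filter_homology(hom, max_evalue = max_evalue, top_n = top_n)
}

#' Filter a homology table
#'
#' The filtering core of [read_homology()], applicable to an in-memory table.
#' Idempotent: applying it to its own output changes nothing.
#'
#' @param hom data.frame `gene_a`, `gene_b`, `evalue`, `bitscore`.
#' @inheritParams read_homology
#' @return filtered data.frame with unordered-deduplicated pairs.
#' @export
filter_homology <- function(hom, max_evalue = 1e-10, top_n = 5L) {
  hom <- hom[hom$gene_a != hom$gene_b & hom$evalue <= max_evalue, , drop = FALSE]
  if (nrow(hom) == 0) return(hom[, c("gene_a", "gene_b", "evalue", "bitscore")])
  # trim every gene's partner list to its top_n, over the symmetrised hit
  # list; a pair survives only if it survives in both lists
  sym <- rbind(hom, data.frame(gene_a = hom$gene_b, gene_b = hom$gene_a,
                               evalue = hom$evalue, bitscore = hom$bitscore))
  sym <- sym[order(sym$gene_a, sym$gene_b, sym$evalue, -sym$bitscore), , drop = FALSE]
  sym <- sym[!duplicated(sym[, c("gene_a", "gene_b")]), , drop = FALSE]
  sym <- sym[order(sym$gene_a, sym$evalue, -sym$bitscore, sym$gene_b), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(sym)), sym$gene_a),
                        function(i) utils::head(i, top_n)), use.names = FALSE)
  sym <- sym[sort(keep), , drop = FALSE]
  key <- paste(sym$gene_a, sym$gene_b, sep = "\r")
  rev_key <- paste(sym$gene_b, sym$gene_a, sep = "\r")
  sym <- sym[rev_key %in% key, , drop = FALSE]
  a <- pmin(sym$gene_a, sym$gene_b)
  b <- pmax(sym$gene_a, sym$gene_b)
  out <- data.frame(gene_a = a, gene_b = b, evalue = sym$evalue, bitscore = sym$bitscore)
  out <- out[order(out$gene_a, out$gene_b, out$evalue), , drop = FALSE]
  out <- out[!duplicated(out[, c("gene_a", "gene_b")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a homology table to TSV
#' @param hom homology data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_homology <- function(hom, path) {
  utils::write.table(hom, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct an expression matrix
#'
#' TPM values per gene, sample and replicate, stored as a genes x columns
#' matrix with column names `<sample>_r<k>`. Every sample must carry the same
#' number of replicates.
#'
#' @param values numeric matrix, rownames gene ids, colnames `<sample>_r<k>`.
#' @return an object of class `expression_matrix`.
#' @export
new_expression_matrix <- function(values) {
  if (any(values < 0)) stop("negative TPM value", call. = FALSE)
  cn <- colnames(values)
  m <- regmatches(cn, regexec("^(.*)_r(\\d+)$", cn))
  if (any(lengths(m) != 3))
    stop("column names must look like '<sample>_r<k>'", call. = FALSE)
  samples <- vapply(m, `[`, character(1), 2)
  reps <- table(samples)
  if (length(unique(reps)) != 1) {
    off <- names(reps)[reps != max(reps)]
    stop("inconsistent replicate count for sample(s): ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  structure(values, class = c("expression_matrix", "matrix", "array"),
            samples = unique(samples), replicates = unname(reps[1]))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix>", nrow(x), "genes x", length(attr(x, "samples")),
      "samples x", attr(x, "replicates"), "replicates (TPM)\n")
  invisible(x)
}

#' Samples of an expression matrix
#' @param expr an `expression_matrix`.
#' @return character vector of sample labels.
#' @export
expr_samples <- function(expr) attr(expr, "samples")

#' Replicate TPM values of one gene in one sample
#' @param expr an `expression_matrix`.
#' @param gene gene id.
#' @param sample sample label.
#' @return numeric vector of replicate TPMs.
#' @export
expr_replicates <- function(expr, gene, sample) {
  cols <- grep(paste0("^", sample, "_r\\d+$"), colnames(expr))
  unname(expr[gene, cols])
}

#' Read a replicate expression table
#'
#' TSV with a `gene` first column then `<sample>_r<k>` numeric columns.
#' Missing genes are simply absent (not zero-filled); negative values and
#' unequal per-sample replicate counts are hard errors.
#'
#' @param path TSV file with header.
#' @return an `expression_matrix`.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") stop("first column must be 'gene'", call. = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression value", call. = FALSE)
  rownames(vals) <- df$gene
  new_expression_matrix(vals)
}

#' Write an expression matrix to TSV
#' @param expr an `expression_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), unclass(expr), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
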