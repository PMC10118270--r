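# Codon-level lookup tables shared by the Ka/Ks estimator and the sequence
# simulator. Built once per session by brute-force enumeration over the
# standard genetic code and cached; all downstream pair computations are
# table lookups.

.codon_cache <- new.env(parent = emptyenv())

codon_index <- function(codons) match(codons, codon_tables()$codons)

#' @keywords internal
codon_tables <- function() {
  if (!is.null(.codon_cache$tables)) return(.codon_cache$tables)
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- sort(codons)
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  is_stop <- aa == "*"
  nc <- length(codons)

  # single-mutation neighbours: neighbour[[i]] rows (pos, new base, codon j, syn)
  neighbours <- vector("list", nc)
  for (i in seq_len(nc)) {
    cs <- strsplit(codons[i], "")[[1]]
    rows <- list()
    for (pos in 1:3) {
      for (b in setdiff(bases, cs[pos])) {
        mut <- cs
        mut[pos] <- b
        j <- match(paste(mut, collapse = ""), codons)
        rows[[length(rows) + 1L]] <- data.frame(
          pos = pos, base = b, to = j,
          syn = !is_stop[i] && !is_stop[j] && aa[i] == aa[j],
          to_stop = is_stop[j]
        )
      }
    }
    neighbours[[i]] <- do.call(rbind, rows)
  }

  # NG86 synonymous site count per codon: per position, (synonymous changes)/3.
  # Changes to stop codons count as nonsynonymous (they are not synonymous and
  # the site still exists); stop codons themselves carry 0 sites.
  syn_sites <- vapply(seq_len(nc), function(i) {
    if (is_stop[i]) return(0)
    sum(neighbours[[i]]$syn) / 3
  }, numeric(1))

  # pathway-averaged synonymous/nonsynonymous difference counts per codon pair
  sd_mat <- matrix(0, nc, nc)
  nd_mat <- matrix(0, nc, nc)
  perms2 <- list(c(1, 2), c(2, 1))
  perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  split_codons <- strsplit(codons, "")
  step_class <- function(i, j) {
    # one-step change i -> j: c(syn, nonsyn)
    if (aa[i] != "*" && aa[j] != "*" && aa[i] == aa[j]) c(1, 0) else c(0, 1)
  }
  for (i in seq_len(nc)) {
    for (j in seq_len(nc)) {
      if (i >= j || is_stop[i] || is_stop[j]) next
      diffs <- which(split_codons[[i]] != split_codons[[j]])
      d <- length(diffs)
      if (d == 0) next
      perms <- switch(d, list(1L), perms2, perms3)
      paths <- matrix(0, 0, 2)
      blocked <- matrix(0, 0, 2)
      for (p in perms) {
        cur <- i
        counts <- c(0, 0)
        through_stop <- FALSE
        for (step in p) {
          pos <- diffs[step]
          nxt <- split_codons[[cur]]
          nxt[pos] <- split_codons[[j]][pos]
          nxt_i <- match(paste(nxt, collapse = ""), codons)
          counts <- counts + step_class(cur, nxt_i)
          if (is_stop[nxt_i]) through_stop <- TRUE
          cur <- nxt_i
        }
        if (through_stop) blocked <- rbind(blocked, counts) else paths <- rbind(paths, counts)
      }
      use <- if (nrow(paths) > 0) paths else blocked  # all-blocked fallback
      sd_mat[i, j] <- sd_mat[j, i] <- mean(use[, 1])
      nd_mat[i, j] <- nd_mat[j, i] <- mean(use[, 2])
    }
  }

  .codon_cache$tables <- list(
    codons = codons, aa = aa, is_stop = is_stop,
    neighbours = neighbours, syn_sites = syn_sites,
    sd = sd_mat, nd = nd_mat
  )
  .codon_cache$tables
}

# split an in-frame CDS string into codon indices (NA for codons containing
# ambiguity characters)
cds_to_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("CDS length ", n, " is not a multiple of 3", call. = FALSE)
  starts <- seq(1L, n, by = 3L)
  codons <- substring(toupper(seq), starts, starts + 2L)
  codon_index(codons)
}

codons_to_cds <- function(idx) {
  paste(codon_tables()$codons[idx], collapse = "")
}
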