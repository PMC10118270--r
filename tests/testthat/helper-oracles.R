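# Independent oracles, written against the definitions rather than the
# package internals.

# --- NG86 reference implementation (recursive pathway enumeration) --------

.oracle_code <- local({
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  list(bases = bases, codons = codons, aa = setNames(aa, codons))
})

oracle_syn_sites <- function(codon) {
  aa <- .oracle_code$aa
  if (aa[[codon]] == "*") return(0)
  s <- 0
  cs <- strsplit(codon, "")[[1]]
  for (pos in 1:3) {
    for (b in setdiff(.oracle_code$bases, cs[pos])) {
      mut <- cs; mut[pos] <- b
      mut <- paste(mut, collapse = "")
      if (aa[[mut]] != "*" && aa[[mut]] == aa[[codon]]) s <- s + 1 / 3
    }
  }
  s
}

# all minimal pathways between two codons; returns c(Sd, Nd) averaged over
# pathways avoiding stops (all pathways if every one is blocked)
oracle_pair_diffs <- function(c1, c2) {
  aa <- .oracle_code$aa
  diffs <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(diffs) == 0) return(c(0, 0))
  perms <- combinat_perms(diffs)
  clean <- list(); blocked <- list()
  for (p in perms) {
    cur <- strsplit(c1, "")[[1]]
    tgt <- strsplit(c2, "")[[1]]
    sd <- nd <- 0; hit_stop <- FALSE
    for (pos in p) {
      prev <- paste(cur, collapse = "")
      cur[pos] <- tgt[pos]
      nxt <- paste(cur, collapse = "")
      if (aa[[nxt]] == "*") hit_stop <- TRUE
      if (aa[[prev]] != "*" && aa[[nxt]] != "*" && aa[[prev]] == aa[[nxt]])
        sd <- sd + 1 else nd <- nd + 1
    }
    rec <- c(sd, nd)
    if (hit_stop) blocked[[length(blocked) + 1]] <- rec
    else clean[[length(clean) + 1]] <- rec
  }
  use <- if (length(clean) > 0) clean else blocked
  colMeans(do.call(rbind, use))
}

combinat_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in combinat_perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

# full NG86 + Jukes-Cantor on two aligned CDS strings
oracle_ka_ks <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  aa <- .oracle_code$aa
  keep <- ca %in% .oracle_code$codons & cb %in% .oracle_code$codons &
    aa[ca] != "*" & aa[cb] != "*"
  ca <- ca[keep]; cb <- cb[keep]
  S <- (sum(vapply(ca, oracle_syn_sites, numeric(1))) +
        sum(vapply(cb, oracle_syn_sites, numeric(1)))) / 2
  N <- 3 * length(ca) - S
  d <- rowSums(vapply(seq_along(ca), function(i) oracle_pair_diffs(ca[i], cb[i]),
                      numeric(2)))
  pS <- d[1] / S; pN <- d[2] / N
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = d[1], Nd = d[2], pS = pS, pN = pN,
       Ks = if (pS < 0.75) jc(pS) else NA_real_,
       Ka = if (pN < 0.75) jc(pN) else NA_real_)
}

# --- exhaustive maximum-score collinear chain -----------------------------

# anchors: data.frame(rank_a, rank_b, score); returns the maximum chain
# score over both orientations under the linear gap penalty, by DFS over all
# chains (feasible for <= 12 anchors)
oracle_best_chain_score <- function(anchors, max_gap = 25, gap_penalty = 1) {
  n <- nrow(anchors)
  if (n == 0) return(list(score = -Inf, len = 0L))
  best <- -Inf
  best_len <- 0L
  for (orient in c(1, -1)) {
    rb <- orient * anchors$rank_b
    extend <- function(i, score, len) {
      if (score > best || (score == best && len > best_len)) {
        best <<- score
        best_len <<- len
      }
      for (j in seq_len(n)) {
        ga <- anchors$rank_a[j] - anchors$rank_a[i] - 1
        gb <- rb[j] - rb[i] - 1
        if (anchors$rank_a[j] > anchors$rank_a[i] && rb[j] > rb[i] &&
            ga <= max_gap && gb <= max_gap)
          extend(j, score + anchors$score[j] - gap_penalty * (ga + gb), len + 1L)
      }
    }
    for (i in seq_len(n)) extend(i, anchors$score[i], 1L)
  }
  list(score = best, len = best_len)
}

random_anchor_instance <- function(n, chrom = "c1") {
  df <- data.frame(
    gene_a = paste0("qa", seq_len(n)), gene_b = paste0("qb", seq_len(n)),
    chrom_a = chrom, chrom_b = chrom,
    rank_a = sample.int(40, n), rank_b = sample.int(40, n),
    score = sample(5:60, n, replace = TRUE))
  df <- df[!duplicated(df[, c("rank_a", "rank_b")]), ]
  attr(df, "self_comparison") <- FALSE
  df
}

# --- misc builders --------------------------------------------------------

toy_genome <- function(name, chroms) {
  # chroms: named list chrom -> vector of gene ids, laid out in order
  rows <- list()
  for (ch in names(chroms)) {
    ids <- chroms[[ch]]
    rows[[ch]] <- data.frame(id = ids, chromosome = ch,
                             start = seq_along(ids) * 1000L,
                             end = seq_along(ids) * 1000L + 500L,
                             strand = "+")
  }
  new_genome(name, do.call(rbind, rows))
}

hom_table <- function(pairs, evalue = 1e-50, bitscore = 100) {
  if (length(pairs) == 0)
    return(data.frame(gene_a = character(), gene_b = character(),
                      evalue = numeric(), bitscore = numeric()))
  data.frame(gene_a = vapply(pairs, `[`, character(1), 1),
             gene_b = vapply(pairs, `[`, character(1), 2),
             evalue = evalue, bitscore = bitscore)
}

# a subgenome_assignment built directly from simulation truth (bypasses
# synteny detection; used to test the window/bias statistics in isolation)
truth_assignment <- function(ds, lineage = "lineage2x") {
  tg <- ds$truth$genes
  base <- tg[tg$genome == lineage & tg$origin %in% c("wgd", "addition"), ]
  labels <- sort(unique(base$subgenome))
  labels <- intersect(c("LF", "MF", "MF1", "MF2"), labels)
  g <- ds$ref$genes
  presence <- data.frame(id = g$id, chromosome = g$chromosome, rank = g$rank)
  for (lab in labels) {
    retained <- g$id %in% base$ancestral_id[base$subgenome == lab]
    presence[[paste0("covered_", lab)]] <- TRUE
    presence[[paste0("retained_", lab)]] <- retained
  }
  structure(list(reference = ds$ref$name, ploidy = length(labels),
                 labels = labels, tracks = data.frame(),
                 presence = presence,
                 target_gene_labels = data.frame(gene = character(),
                                                 label = character()),
                 flagged_blocks = integer()),
            class = "subgenome_assignment")
}

# random in-frame CDS without internal stops
random_cds <- function(n_codons) {
  sense <- .oracle_code$codons[.oracle_code$aa != "*"]
  paste0("ATG", paste(sample(sense, n_codons - 1, replace = TRUE), collapse = ""))
}
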