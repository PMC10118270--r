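#' Build anchors from a homology table
#'
#' Resolves each surviving homology pair to its gene-order positions in the
#' two genomes. For a self-comparison (`genome_a` and `genome_b` the same
#' genome) identity pairs are excluded and each pair is emitted in both
#' orientations so off-diagonal duplicate blocks can be chained; mirror-image
#' blocks are removed again by [chain_blocks()]. Tandem arrays (runs of
#' adjacent homologous genes on one chromosome) are collapsed to their
#' lowest-rank representative before anchoring, the standard practice to
#' avoid spuriously thick anchors.
#'
#' @param genome_a,genome_b `genome` objects (may be the same object).
#' @param homology filtered homology data.frame (see [read_homology()]); may
#'   contain pairs for other genomes, which are ignored, but a pair
#'   referencing an id found in neither genome is an error.
#' @param collapse_tandem collapse tandem arrays before anchoring.
#' @return data.frame of anchors: `gene_a`, `gene_b`, `chrom_a`, `chrom_b`,
#'   `rank_a`, `rank_b`, `score` (bitscore), with attribute
#'   `self_comparison`.
#' @export
build_anchors <- function(genome_a, genome_b, homology, collapse_tandem = TRUE) {
  self <- identical(genome_a$name, genome_b$name)
  ra <- gene_ranks(genome_a); ca <- gene_chromosomes(genome_a)
  rb <- gene_ranks(genome_b); cb <- gene_chromosomes(genome_b)
  known <- unique(c(names(ra), names(rb)))
  unknown <- setdiff(unique(c(homology$gene_a, homology$gene_b)), known)
  if (length(unknown) > 0)
    stop("homology references unknown gene id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)

  if (collapse_tandem) {
    rep_a <- tandem_representatives(genome_a, homology)
    rep_b <- if (self) rep_a else tandem_representatives(genome_b, homology)
  } else {
    rep_a <- stats::setNames(names(ra), names(ra))
    rep_b <- stats::setNames(names(rb), names(rb))
  }

  in_a <- homology$gene_a %in% names(ra) & homology$gene_b %in% names(rb)
  in_b <- homology$gene_a %in% names(rb) & homology$gene_b %in% names(ra)
  h1 <- homology[in_a, , drop = FALSE]
  h2 <- homology[in_b & !in_a, , drop = FALSE]  # flip to put side A first
  hom <- rbind(h1, data.frame(gene_a = h2$gene_b, gene_b = h2$gene_a,
                              evalue = h2$evalue, bitscore = h2$bitscore))
  if (self) {  # emit both orientations
    hom <- rbind(hom, data.frame(gene_a = hom$gene_b, gene_b = hom$gene_a,
                                 evalue = hom$evalue, bitscore = hom$bitscore))
  }
  hom$gene_a <- unname(rep_a[hom$gene_a])
  hom$gene_b <- unname(rep_b[hom$gene_b])
  if (self) hom <- hom[hom$gene_a != hom$gene_b, , drop = FALSE]
  # deduplicate collapsed pairs, keeping the best score
  hom <- hom[order(hom$gene_a, hom$gene_b, -hom$bitscore), , drop = FALSE]
  hom <- hom[!duplicated(hom[, c("gene_a", "gene_b")]), , drop = FALSE]
  anchors <- data.frame(
    gene_a = hom$gene_a, gene_b = hom$gene_b,
    chrom_a = unname(ca[hom$gene_a]), chrom_b = unname(cb[hom$gene_b]),
    rank_a = unname(ra[hom$gene_a]), rank_b = unname(rb[hom$gene_b]),
    score = hom$bitscore
  )
  anchors <- anchors[order(anchors$chrom_a, anchors$chrom_b,
                           anchors$rank_a, anchors$rank_b), , drop = FALSE]
  rownames(anchors) <- NULL
  attr(anchors, "self_comparison") <- self
  anchors
}

# map each gene to the lowest-rank member of its tandem array (connected runs
# of same-chromosome homologous genes at adjacent ranks), using the
# within-genome pairs present in the homology table
tandem_representatives <- function(genome, homology) {
  ids <- genome$genes$id
  reps <- stats::setNames(ids, ids)
  r <- gene_ranks(genome); ch <- gene_chromosomes(genome)
  within <- homology$gene_a %in% ids & homology$gene_b %in% ids
  h <- homology[within, c("gene_a", "gene_b")]
  if (nrow(h) == 0) return(reps)
  adj <- h[ch[h$gene_a] == ch[h$gene_b] & abs(r[h$gene_a] - r[h$gene_b]) == 1L, ,
           drop = FALSE]
  if (nrow(adj) == 0) return(reps)
  # union by rank order: iterate pairs sorted by rank so chains resolve to
  # their lowest-rank member in one pass
  lo <- ifelse(r[adj$gene_a] < r[adj$gene_b], adj$gene_a, adj$gene_b)
  hi <- ifelse(r[adj$gene_a] < r[adj$gene_b], adj$gene_b, adj$gene_a)
  ord <- order(ch[lo], r[lo])
  for (k in ord) reps[[hi[k]]] <- reps[[lo[k]]]
  reps
}

#' Chain anchors into collinear blocks
#'
#' MCscan-style dynamic programming per chromosome pair and orientation:
#' chains maximize summed anchor score minus a linear gap penalty
#' (`gap_penalty` per skipped gene on either genome), with consecutive
#' anchors at most `max_gap` genes apart on each side and ranks strictly
#' monotonic (increasing on both sides, or increasing/decreasing for
#' inverted blocks). Chains are extracted best-first; anchors of an
#' extracted chain are consumed and the remainder re-chained; chains shorter
#' than `min_span` anchors are discarded.
#'
#' @param anchors anchor data.frame from [build_anchors()].
#' @param min_span minimum anchors per block (4 for microsynteny, 30 for
#'   macrosynteny).
#' @param max_gap maximum rank gap between consecutive anchors.
#' @param gap_penalty score penalty per skipped gene.
#' @return object of class `collinear_blocks`: list with `blocks` (one row
#'   per block: id, chromosomes, orientation, `n_anchors`, 0-based half-open
#'   rank spans, score) and `anchors` (input anchors with `block_id`).
#' @export
chain_blocks <- function(anchors, min_span = 4L, max_gap = 25L, gap_penalty = 1) {
  if (min_span < 2) stop("min_span must be >= 2", call. = FALSE)
  self <- isTRUE(attr(anchors, "self_comparison"))
  empty <- data.frame(block_id = integer(), chrom_a = character(),
                      chrom_b = character(), orientation = character(),
                      n_anchors = integer(), start_a = integer(), end_a = integer(),
                      start_b = integer(), end_b = integer(), score = numeric())
  anchors$block_id <- rep(NA_integer_, nrow(anchors))
  if (nrow(anchors) == 0)
    return(structure(list(blocks = empty, anchors = anchors),
                     class = "collinear_blocks"))

  groups <- split(seq_len(nrow(anchors)),
                  paste(anchors$chrom_a, anchors$chrom_b, sep = "\r"))
  blocks <- list()
  bid <- 0L
  for (idx in groups) {
    live <- idx
    while (length(live) > 0) {
      best <- NULL
      for (orient in c("same", "inverted")) {
        ch <- best_chain(anchors$rank_a[live], anchors$rank_b[live],
                         anchors$score[live], orient, max_gap, gap_penalty)
        if (is.null(ch)) next
        if (is.null(best) || ch$score > best$score ||
            (ch$score == best$score &&
             chain_tiebreak(anchors, live[ch$members], live[best$members]))) {
          best <- ch
          best$orientation <- orient
        }
      }
      if (is.null(best)) break
      members <- live[best$members]
      if (length(members) >= min_span) {
        bid <- bid + 1L
        anchors$block_id[members] <- bid
        blocks[[bid]] <- data.frame(
          block_id = bid,
          chrom_a = anchors$chrom_a[members[1]],
          chrom_b = anchors$chrom_b[members[1]],
          orientation = best$orientation,
          n_anchors = length(members),
          start_a = min(anchors$rank_a[members]),
          end_a = max(anchors$rank_a[members]) + 1L,
          start_b = min(anchors$rank_b[members]),
          end_b = max(anchors$rank_b[members]) + 1L,
          score = best$score
        )
      }
      live <- setdiff(live, members)
    }
  }
  blocks <- if (length(blocks) > 0) do.call(rbind, blocks) else empty
  if (self && nrow(blocks) > 0) {
    # drop self blocks whose two spans overlap on one chromosome: these are
    # near-diagonal chains of single-gene duplicates (the identity-diagonal
    # artifact generalized), not duplicated segments
    diag_art <- blocks$chrom_a == blocks$chrom_b &
      blocks$start_a < blocks$end_b & blocks$start_b < blocks$end_a
    anchors$block_id[anchors$block_id %in% blocks$block_id[diag_art]] <- NA_integer_
    blocks <- blocks[!diag_art, , drop = FALSE]
  }
  if (self && nrow(blocks) > 0) {
    # drop mirror images of off-diagonal self blocks
    sa <- paste(blocks$chrom_a, blocks$start_a, blocks$end_a)
    sb <- paste(blocks$chrom_b, blocks$start_b, blocks$end_b)
    key <- paste(pmin(sa, sb), pmax(sa, sb), blocks$orientation)
    keep <- !duplicated(key)
    dropped <- blocks$block_id[!keep]
    blocks <- blocks[keep, , drop = FALSE]
    anchors$block_id[anchors$block_id %in% dropped] <- NA_integer_
  }
  rownames(blocks) <- NULL
  structure(list(blocks = blocks, anchors = anchors), class = "collinear_blocks")
}

#' @export
print.collinear_blocks <- function(x, ...) {
  cat("<collinear_blocks>", nrow(x$blocks), "blocks,",
      sum(!is.na(x$anchors$block_id)), "of", nrow(x$anchors),
      "anchors assigned\n")
  invisible(x)
}

# prefer the chain whose first anchor has smaller (rank_a, rank_b)
chain_tiebreak <- function(anchors, new_members, old_members) {
  n1 <- new_members[1]; o1 <- old_members[1]
  anchors$rank_a[n1] < anchors$rank_a[o1] ||
    (anchors$rank_a[n1] == anchors$rank_a[o1] &&
     anchors$rank_b[n1] < anchors$rank_b[o1])
}

# maximum-score chain by DP over anchors of one chromosome pair.
# orientation "same": rank_b strictly increasing; "inverted": decreasing.
# returns list(members = indices into the input vectors in chain order, score)
best_chain <- function(rank_a, rank_b, score, orientation, max_gap, gap_penalty) {
  n <- length(rank_a)
  if (n == 0) return(NULL)
  rb <- if (orientation == "inverted") -rank_b else rank_b
  ord <- order(rank_a, rb)
  ra_s <- rank_a[ord]; rb_s <- rb[ord]; sc_s <- score[ord]
  dp <- sc_s
  len <- rep(1L, n)
  parent <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (i == 1) next
    for (j in seq_len(i - 1)) {
      ga <- ra_s[i] - ra_s[j] - 1L
      gb <- abs(rb_s[i] - rb_s[j]) - 1L
      if (ra_s[j] >= ra_s[i] || rb_s[j] >= rb_s[i]) next
      if (ga > max_gap || gb > max_gap) next
      cand <- dp[j] + sc_s[i] - gap_penalty * (ga + gb)
      # on a score tie, prefer the longer chain
      if (cand > dp[i] || (cand == dp[i] && len[j] + 1L > len[i])) {
        dp[i] <- cand
        len[i] <- len[j] + 1L
        parent[i] <- j
      }
    }
  }
  end <- which(dp == max(dp))
  # tie-break: longest chain, then smaller chain start (rank_a, rank_b)
  if (length(end) > 1) {
    starts <- vapply(end, function(e) {
      while (!is.na(parent[e])) e <- parent[e]
      e
    }, integer(1))
    end <- end[order(-len[end], ra_s[starts], rb_s[starts])][1]
  }
  members <- end
  while (!is.na(parent[members[1]])) members <- c(parent[members[1]], members)
  list(members = ord[members], score = max(dp))
}

#' Per-gene syntenic depth
#'
#' For each gene of one genome, the number of collinear blocks whose rank
#' interval on that side contains the gene's rank. The modal depth over
#' covered genes is the genome-equivalent signal (1x/2x/3x).
#'
#' @param blocks a `collinear_blocks` object.
#' @param genome the `genome` whose side is profiled.
#' @param side `"a"` or `"b"`: which side of the blocks corresponds to
#'   `genome`.
#' @return object of class `depth_profile`: list with `genes` (id,
#'   chromosome, rank, depth), `histogram` and `modal_depth`.
#' @export
compute_depth <- function(blocks, genome, side = c("a", "b")) {
  side <- match.arg(side)
  b <- blocks$blocks
  g <- genome$genes
  depth <- integer(nrow(g))
  if (nrow(b) > 0) {
    chrom_col <- paste0("chrom_", side)
    start_col <- paste0("start_", side)
    end_col <- paste0("end_", side)
    for (k in seq_len(nrow(b))) {
      hit <- g$chromosome == b[[chrom_col]][k] &
        g$rank >= b[[start_col]][k] & g$rank < b[[end_col]][k]
      depth[hit] <- depth[hit] + 1L
    }
  }
  hist <- table(factor(depth, levels = 0:max(c(depth, 6))))
  covered <- depth[depth > 0]
  modal <- if (length(covered) > 0)
    as.integer(names(which.max(table(covered)))) else 0L
  structure(list(
    genes = data.frame(id = g$id, chromosome = g$chromosome, rank = g$rank,
                       depth = depth),
    histogram = hist,
    modal_depth = modal
  ), class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat("<depth_profile>", nrow(x$genes), "genes, modal depth", x$modal_depth, "\n")
  print(x$histogram)
  invisible(x)
}

#' Summarize a pair of depth profiles as a syntenic depth ratio
#'
#' Given the two per-genome depth profiles of one genome comparison, reports
#' the modal depths and the percentage of genes at depths 0..6+ on each
#' side. The genome-equivalent ratio `x:y` for genomes (A, B) takes `x` =
#' modal depth observed over B's genes (how many A blocks cover a B gene)
#' and `y` = modal depth over A's genes, so a 1x reference versus a
#' tetraploid-derived genome reads `1:2`.
#'
#' @param profile_a depth profile of genome A's genes (covered by B blocks).
#' @param profile_b depth profile of genome B's genes.
#' @return list with `ratio` (named c(x, y)), `ratio_label`, per-side depth
#'   percentage tables, and `undefined` flag (no covered genes on a side).
#' @export
summarize_depth_ratio <- function(profile_a, profile_b) {
  pct <- function(p) {
    d <- pmin(p$genes$depth, 6L)
    100 * table(factor(d, levels = 0:6)) / nrow(p$genes)
  }
  undefined <- profile_a$modal_depth == 0 || profile_b$modal_depth == 0
  ratio <- c(x = profile_b$modal_depth, y = profile_a$modal_depth)
  structure(list(
    ratio = ratio,
    ratio_label = if (undefined) "undefined" else paste0(ratio["x"], ":", ratio["y"]),
    pct_a = pct(profile_a),
    pct_b = pct(profile_b),
    undefined = undefined
  ), class = "depth_ratio_summary")
}

#' @export
print.depth_ratio_summary <- function(x, ...) {
  cat("<depth_ratio_summary> ratio", x$ratio_label, "\n")
  invisible(x)
}

#' Write blocks to a TSV file
#' @param blocks a `collinear_blocks` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_blocks <- function(blocks, path) {
  b <- blocks$blocks
  out <- data.frame(block_id = b$block_id, chrom_a = b$chrom_a, chrom_b = b$chrom_b,
                    orientation = b$orientation, n_anchors = b$n_anchors,
                    ranks_a = paste0("[", b$start_a, ",", b$end_a, ")"),
                    ranks_b = paste0("[", b$start_b, ",", b$end_b, ")"),
                    score = b$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
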