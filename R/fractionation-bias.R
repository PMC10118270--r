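#' Assign target collinear blocks to subgenome tracks
#'
#' Against a 1x reference, the blocks of a polyploid target genome are packed
#' per reference chromosome into `ploidy` non-overlapping tracks (interval
#' scheduling on reference rank spans, preferring to keep blocks from the
#' same target chromosome in one track, since subgenomes are
#' chromosome-scale objects). Tracks are then ranked by retained gene count
#' and labelled `LF` >= `MF` (ploidy 2) or `LF` >= `MF1` >= `MF2` (ploidy 3).
#' Blocks exceeding the ploidy depth at a locus are flagged, not dropped
#' silently.
#'
#' @param reference the 1x reference `genome` (side "a" of the blocks).
#' @param blocks `collinear_blocks` from a reference-vs-target comparison.
#' @param ploidy expected genome-equivalent count of the target (2 or 3).
#' @return object of class `subgenome_assignment`: list with `tracks` (block
#'   to label), `presence` (per reference gene, covered/retained flags per
#'   label), `target_gene_labels` (target anchor gene to label) and
#'   `flagged_blocks`.
#' @export
assign_subgenomes <- function(reference, blocks, ploidy) {
  if (!ploidy %in% c(2L, 3L)) stop("ploidy must be 2 or 3", call. = FALSE)
  labels <- if (ploidy == 2L) c("LF", "MF") else c("LF", "MF1", "MF2")
  b <- blocks$blocks
  anch <- blocks$anchors[!is.na(blocks$anchors$block_id), , drop = FALSE]
  g <- reference$genes

  # overflow diagnostic: local depth above ploidy
  depth <- compute_depth(blocks, reference, side = "a")
  over <- mean(depth$genes$depth > ploidy)
  if (over > 0.10)
    warning(sprintf("local syntenic depth exceeds ploidy %d for %.0f%% of reference genes",
                    ploidy, 100 * over), call. = FALSE)

  track_rows <- list()
  flagged <- integer()
  for (chrom in unique(g$chromosome)) {
    cb <- b[b$chrom_a == chrom, , drop = FALSE]
    if (nrow(cb) == 0) next
    # pack target chromosomes (groups of blocks) in descending total score,
    # keeping each group in one slot where possible: subgenomes are
    # chromosome-scale, so spurious low-scoring chains of leftover duplicate
    # anchors only fit where a slot has room left
    slot_iv <- replicate(ploidy, matrix(numeric(0), ncol = 2), simplify = FALSE)
    slot_targets <- replicate(ploidy, character(0), simplify = FALSE)
    slot_of <- rep(NA_integer_, nrow(cb))
    fits_slot <- function(s, start, end) {
      iv <- slot_iv[[s]]
      nrow(iv) == 0 || all(iv[, 2] <= start | iv[, 1] >= end)
    }
    grp_score <- tapply(cb$score, cb$chrom_b, sum)
    for (tchrom in names(sort(grp_score, decreasing = TRUE))) {
      gi <- which(cb$chrom_b == tchrom)
      gi <- gi[order(-cb$score[gi])]
      # choose the slot that accommodates the most of this group's blocks,
      # preferring slots already holding this target chromosome
      n_fit <- vapply(seq_len(ploidy), function(s)
        sum(vapply(gi, function(i) fits_slot(s, cb$start_a[i], cb$end_a[i]),
                   logical(1))), integer(1))
      pref <- vapply(seq_len(ploidy), function(s)
        tchrom %in% slot_targets[[s]], logical(1))
      home <- order(-n_fit, !pref)[1]
      for (i in gi) {
        # a group block that collides with its own group's slot is a
        # duplicate chain over the same reference region (excess depth);
        # flag it rather than let it displace another subgenome's slot
        if (!fits_slot(home, cb$start_a[i], cb$end_a[i])) {
          flagged <- c(flagged, cb$block_id[i])
          next
        }
        slot_of[i] <- home
        slot_iv[[home]] <- rbind(slot_iv[[home]], c(cb$start_a[i], cb$end_a[i]))
        slot_targets[[home]] <- union(slot_targets[[home]], cb$chrom_b[i])
      }
    }
    for (s in seq_len(ploidy)) {
      ids <- cb$block_id[!is.na(slot_of) & slot_of == s]
      if (length(ids) == 0) next
      track_rows[[length(track_rows) + 1L]] <- data.frame(
        chrom_a = chrom, slot = s, block_id = ids,
        chrom_b = b$chrom_b[match(ids, b$block_id)])
    }
  }
  tracks <- if (length(track_rows) > 0) do.call(rbind, track_rows)
    else data.frame(chrom_a = character(), slot = integer(),
                    block_id = integer(), chrom_b = character())

  # per-chromosome slot -> label by retained gene count
  presence <- data.frame(id = g$id, chromosome = g$chromosome, rank = g$rank)
  for (lab in labels) {
    presence[[paste0("covered_", lab)]] <- FALSE
    presence[[paste0("retained_", lab)]] <- FALSE
  }
  tracks$label <- NA_character_
  target_labels <- list()
  for (chrom in unique(tracks$chrom_a)) {
    tr <- tracks[tracks$chrom_a == chrom, , drop = FALSE]
    gsel <- presence$chromosome == chrom
    slot_ret <- vapply(sort(unique(tr$slot)), function(s) {
      ids <- tr$block_id[tr$slot == s]
      length(unique(anch$gene_a[anch$block_id %in% ids]))
    }, integer(1))
    ord <- sort(unique(tr$slot))[order(-slot_ret)]
    for (k in seq_along(ord)) {
      lab <- labels[k]
      s <- ord[k]
      ids <- tr$block_id[tr$slot == s]
      tracks$label[tracks$chrom_a == chrom & tracks$slot == s] <- lab
      bsel <- b[b$block_id %in% ids, , drop = FALSE]
      cov <- rep(FALSE, sum(gsel))
      rks <- presence$rank[gsel]
      for (i in seq_len(nrow(bsel)))
        cov <- cov | (rks >= bsel$start_a[i] & rks < bsel$end_a[i])
      presence[[paste0("covered_", lab)]][gsel] <- cov
      ret_genes <- unique(anch$gene_a[anch$block_id %in% ids])
      presence[[paste0("retained_", lab)]][gsel] <-
        presence$id[gsel] %in% ret_genes
      tg <- unique(anch$gene_b[anch$block_id %in% ids])
      if (length(tg) > 0)
        target_labels[[length(target_labels) + 1L]] <-
          data.frame(gene = tg, label = lab)
    }
  }
  target_gene_labels <- if (length(target_labels) > 0) {
    tl <- do.call(rbind, target_labels)
    tl[!duplicated(tl$gene), , drop = FALSE]
  } else data.frame(gene = character(), label = character())

  structure(list(reference = reference$name, ploidy = ploidy, labels = labels,
                 tracks = tracks, presence = presence,
                 target_gene_labels = target_gene_labels,
                 flagged_blocks = unique(flagged)),
            class = "subgenome_assignment")
}

#' @export
print.subgenome_assignment <- function(x, ...) {
  cat("<subgenome_assignment> reference", x$reference, "- ploidy", x$ploidy, "\n")
  for (lab in x$labels)
    cat(sprintf("  %-4s %5d blocks-retained genes\n", lab,
                sum(x$presence[[paste0("retained_", lab)]])))
  invisible(x)
}

#' Sliding-window retention profile
#'
#' Per subgenome track, the percent of reference genes in each sliding
#' window of `window` genes (step `step`) that have a retained syntelog in
#' that track. Terminal windows shorter than `window` keep their true size.
#' Genome-wide retention is reported with two denominators: all reference
#' genes, and only reference genes covered by the track's blocks.
#'
#' @param assignment a `subgenome_assignment`.
#' @param window window size in genes (default 100).
#' @param step step in genes (default 10).
#' @return object of class `retention_profile`: list with `windows`
#'   (chrom, window_start_rank, window_size, track, retained_pct),
#'   `genome_wide` (track, retained_pct_all, retained_pct_covered) and the
#'   parameters.
#' @export
retention_windows <- function(assignment, window = 100L, step = 10L) {
  p <- assignment$presence
  labels <- assignment$labels
  rows <- list()
  for (chrom in unique(p$chromosome)) {
    sel <- p[p$chromosome == chrom, , drop = FALSE]
    sel <- sel[order(sel$rank), , drop = FALSE]
    n <- nrow(sel)
    truncated <- n < window
    starts <- if (truncated) 0L else seq(0L, n - window, by = step)
    if (!truncated && max(starts) + window < n) {
      extra <- seq(max(starts) + step, n - 1L, by = step)
      starts <- c(starts, extra)
    }
    for (s in starts) {
      wsel <- sel$rank >= s & sel$rank < s + window
      wsize <- sum(wsel)
      for (lab in labels) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, window_start_rank = s, window_size = wsize,
          track = lab, truncated = truncated || wsize < window,
          retained_pct = 100 * sum(sel[[paste0("retained_", lab)]][wsel]) / wsize)
      }
    }
  }
  windows <- do.call(rbind, rows)
  genome_wide <- do.call(rbind, lapply(labels, function(lab) {
    ret <- p[[paste0("retained_", lab)]]
    cov <- p[[paste0("covered_", lab)]]
    data.frame(track = lab,
               n_retained = sum(ret),
               n_covered = sum(cov),
               retained_pct_all = 100 * sum(ret) / nrow(p),
               retained_pct_covered = if (sum(cov) > 0) 100 * sum(ret & cov) / sum(cov)
                 else NA_real_)
  }))
  structure(list(windows = windows, genome_wide = genome_wide,
                 window = window, step = step),
            class = "retention_profile")
}

#' @export
print.retention_profile <- function(x, ...) {
  cat("<retention_profile>", nrow(x$windows), "window records\n")
  print(x$genome_wide, row.names = FALSE)
  invisible(x)
}

#' Fractionation-bias summary
#'
#' Genome-wide retention per track, pairwise retention differences, and a
#' two-sided sign test across windows for each track pair (is one track
#' retained more than the other in more windows than chance allows).
#'
#' @param profile a `retention_profile`.
#' @return list with `per_track` and `pairwise` (track_a, track_b,
#'   diff_pct_all, windows_a_higher, windows_b_higher, sign_test_p).
#' @export
summarize_bias <- function(profile) {
  gw <- profile$genome_wide
  if (nrow(gw) < 2) stop("bias summary needs >= 2 tracks", call. = FALSE)
  w <- profile$windows
  # the sign test uses the non-overlapping window subset so window outcomes
  # are independent draws
  indep <- w[w$window_start_rank %% profile$window == 0, , drop = FALSE]
  if (nrow(indep) == 0) indep <- w
  w <- indep
  pairs <- utils::combn(gw$track, 2)
  pw <- list()
  for (k in seq_len(ncol(pairs))) {
    ta <- pairs[1, k]; tb <- pairs[2, k]
    wa <- w$retained_pct[w$track == ta]
    wb <- w$retained_pct[w$track == tb]
    wins_a <- sum(wa > wb); wins_b <- sum(wb > wa)
    p <- if (wins_a + wins_b == 0) 1
      else stats::binom.test(wins_a, wins_a + wins_b, 0.5,
                             alternative = "two.sided")$p.value
    pw[[k]] <- data.frame(
      track_a = ta, track_b = tb,
      diff_pct_all = gw$retained_pct_all[gw$track == ta] -
        gw$retained_pct_all[gw$track == tb],
      windows_a_higher = wins_a, windows_b_higher = wins_b,
      sign_test_p = p)
  }
  list(per_track = gw, pairwise = do.call(rbind, pw))
}
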