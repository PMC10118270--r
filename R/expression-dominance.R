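#' Ohnolog groups of a simulated dataset
#'
#' Syntenic ohnolog pairs (2x lineage) or triads (3x lineage) taken from the
#' truth log: ancestral genes whose base copy survives in every subgenome
#' track of the lineage.
#'
#' @param dataset a `simulated_dataset`.
#' @param lineage lineage name (`"lineage2x"` or `"lineage3x"`).
#' @return data.frame with one row per group: `group`, one column per track
#'   label holding the member gene id.
#' @export
ohnolog_groups_from_truth <- function(dataset, lineage = "lineage2x") {
  tg <- dataset$truth$genes
  tg <- tg[tg$genome == lineage & tg$origin %in% c("wgd", "addition"), , drop = FALSE]
  labels <- sort(unique(tg$subgenome))
  wide <- stats::reshape(tg[, c("ancestral_id", "subgenome", "id")],
                         idvar = "ancestral_id", timevar = "subgenome",
                         direction = "wide")
  names(wide) <- sub("^id\\.", "", names(wide))
  full <- stats::complete.cases(wide[, labels, drop = FALSE])
  wide <- wide[full, , drop = FALSE]
  out <- data.frame(group = wide$ancestral_id, wide[, labels, drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Ohnolog groups from a subgenome assignment
#'
#' Reference genes retaining a syntelog in every track yield one group whose
#' members are the target genes anchored to that reference gene, one per
#' track.
#'
#' @param assignment a `subgenome_assignment`.
#' @param blocks the `collinear_blocks` the assignment was computed from.
#' @return data.frame as in [ohnolog_groups_from_truth()].
#' @export
ohnolog_groups_from_assignment <- function(assignment, blocks) {
  anch <- blocks$anchors[!is.na(blocks$anchors$block_id), , drop = FALSE]
  block_label <- stats::setNames(assignment$tracks$label,
                                 assignment$tracks$block_id)
  anch$label <- block_label[as.character(anch$block_id)]
  anch <- anch[!is.na(anch$label), , drop = FALSE]
  labels <- assignment$labels
  # one member per (reference gene, track); drop ambiguous multi-anchors
  anch <- anch[!duplicated(anch[, c("gene_a", "label")]), , drop = FALSE]
  wide <- stats::reshape(anch[, c("gene_a", "label", "gene_b")],
                         idvar = "gene_a", timevar = "label",
                         direction = "wide")
  names(wide) <- sub("^gene_b\\.", "", names(wide))
  missing_lab <- setdiff(labels, names(wide))
  for (lab in missing_lab) wide[[lab]] <- NA_character_
  full <- stats::complete.cases(wide[, labels, drop = FALSE])
  wide <- wide[full, , drop = FALSE]
  out <- data.frame(group = wide$gene_a, wide[, labels, drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Dominance test for one ohnolog group in one sample
#'
#' The "horserace" rule: for pairs, an equal-variance two-sided Student
#' t-test on the replicate TPMs; the higher-mean member is dominant iff
#' p <= alpha. For triads, a member is dominant iff it has the top mean and
#' beats each other member in a pairwise test at alpha (alternative rule
#' `"pooled"`: the top member is tested against the pooled replicates of the
#' other two). Groups with all-equal degenerate replicates give no call;
#' zero-variance groups with unequal means are called dominant with p = 0
#' and flagged.
#'
#' @param members named character vector: track label -> gene id (2 or 3).
#' @param expr an `expression_matrix`.
#' @param sample sample label.
#' @param alpha significance level (default 0.05).
#' @param triad_rule `"beat_both"` (default) or `"pooled"`.
#' @return data.frame row: `sample`, `dominant` (track label or `NA`), `t`,
#'   `p`, `degenerate`.
#' @export
test_ohnolog_group <- function(members, expr, sample, alpha = 0.05,
                               triad_rule = c("beat_both", "pooled")) {
  triad_rule <- match.arg(triad_rule)
  if (!all(members %in% rownames(expr)))
    stop("group member(s) missing from expression matrix: ",
         paste(setdiff(members, rownames(expr)), collapse = ", "), call. = FALSE)
  reps <- lapply(members, function(g) expr_replicates(expr, g, sample))
  means <- vapply(reps, mean, numeric(1))
  top <- which.max(means)

  pair_test <- function(x, y) {
    # equal-variance Student's t; degenerate-variance handling as documented
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (mean(x) == mean(y)) return(list(t = 0, p = 1, degenerate = TRUE))
      return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0, degenerate = TRUE))
    }
    ht <- stats::t.test(x, y, var.equal = TRUE, alternative = "two.sided")
    list(t = unname(ht$statistic), p = ht$p.value, degenerate = FALSE)
  }

  if (length(members) == 2) {
    ht <- pair_test(reps[[1]], reps[[2]])
    dominant <- if (ht$p <= alpha && means[1] != means[2]) names(members)[top]
      else NA_character_
    return(data.frame(sample = sample, dominant = dominant,
                      t = ht$t, p = ht$p, degenerate = ht$degenerate))
  }
  others <- setdiff(seq_along(members), top)
  if (triad_rule == "beat_both") {
    hts <- lapply(others, function(j) pair_test(reps[[top]], reps[[j]]))
    ps <- vapply(hts, `[[`, numeric(1), "p")
    ok <- all(ps <= alpha) && all(means[top] > means[others])
    data.frame(sample = sample,
               dominant = if (ok) names(members)[top] else NA_character_,
               t = max(vapply(hts, `[[`, numeric(1), "t")),
               p = max(ps),
               degenerate = any(vapply(hts, `[[`, logical(1), "degenerate")))
  } else {
    ht <- pair_test(reps[[top]], unlist(reps[others]))
    ok <- ht$p <= alpha && means[top] > max(means[others])
    data.frame(sample = sample,
               dominant = if (ok) names(members)[top] else NA_character_,
               t = ht$t, p = ht$p, degenerate = ht$degenerate)
  }
}

#' Dominance calls for all groups and samples
#'
#' @param groups data.frame from [ohnolog_groups_from_truth()] or
#'   [ohnolog_groups_from_assignment()].
#' @param expr an `expression_matrix`.
#' @param samples sample labels (default: all in `expr`).
#' @inheritParams test_ohnolog_group
#' @return object of class `dominance_calls`: list with `calls` (group,
#'   sample, dominant, t, p, degenerate) and `skipped` (groups with members
#'   missing from the matrix).
#' @export
dominance_calls <- function(groups, expr, samples = expr_samples(expr),
                            alpha = 0.05, triad_rule = c("beat_both", "pooled")) {
  triad_rule <- match.arg(triad_rule)
  labels <- setdiff(names(groups), "group")
  present <- vapply(seq_len(nrow(groups)), function(i)
    all(unlist(groups[i, labels]) %in% rownames(expr)), logical(1))
  skipped <- groups$group[!present]
  rows <- list()
  for (i in which(present)) {
    members <- stats::setNames(as.character(unlist(groups[i, labels])), labels)
    for (s in samples) {
      res <- test_ohnolog_group(members, expr, s, alpha = alpha,
                                triad_rule = triad_rule)
      res$group <- groups$group[i]
      rows[[length(rows) + 1L]] <- res
    }
  }
  calls <- if (length(rows) > 0) do.call(rbind, rows)
    else data.frame(sample = character(), dominant = character(), t = numeric(),
                    p = numeric(), degenerate = logical(), group = character())
  structure(list(calls = calls[, c("group", "sample", "dominant", "t", "p",
                                   "degenerate")],
                 labels = labels, skipped = skipped),
            class = "dominance_calls")
}

#' @export
print.dominance_calls <- function(x, ...) {
  cat("<dominance_calls>", nrow(x$calls), "tests,",
      length(x$skipped), "group(s) skipped\n")
  invisible(x)
}

#' Per-sample dominance percentages
#'
#' For each sample, the percentage of tested groups dominated by each
#' subgenome track, the percentage with any dominant member (the
#' differentially-expressed fraction), and the percentage with none.
#'
#' @param calls a `dominance_calls` object.
#' @return data.frame per sample: one `pct_<label>` column per track,
#'   `pct_any`, `pct_none`, `n_tested`.
#' @export
summarize_dominance <- function(calls) {
  cl <- calls$calls
  labels <- calls$labels
  out <- lapply(unique(cl$sample), function(s) {
    sel <- cl[cl$sample == s, , drop = FALSE]
    n <- nrow(sel)
    row <- data.frame(sample = s, n_tested = n)
    for (lab in labels)
      row[[paste0("pct_", lab)]] <- 100 * sum(sel$dominant == lab, na.rm = TRUE) / n
    row$pct_any <- 100 * sum(!is.na(sel$dominant)) / n
    row$pct_none <- 100 * sum(is.na(sel$dominant)) / n
    row
  })
  do.call(rbind, out)
}
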