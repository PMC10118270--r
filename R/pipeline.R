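#' Analysis configuration
#'
#' All stage parameters with defaults matching the printed constants of the
#' emulated pipeline: homology top-5 at e <= 1e-10, microsynteny minspan 4
#' (macrosynteny 30), 100-gene retention windows, Ks <= 4 for WGD dating
#' (Ks <= 3 for selection summaries), syntelog search with a 40-gene window
#' and 4-gene minimum, 1000 permutation draws, alpha 0.05. Unknown keys are
#' rejected.
#'
#' @param file optional YAML file of overrides (flat keys or per-stage
#'   sections, which are flattened).
#' @param ... key = value overrides applied after the file.
#' @return object of class `analysis_config` (a validated list).
#' @export
analysis_config <- function(file = NULL, ...) {
  cfg <- list(
    max_evalue = 1e-10, top_n = 5L,
    min_span = 4L, min_span_macro = 30L, max_gap = 25L, gap_penalty = 1,
    window = 100L, step = 10L, max_scaffolds = NA,
    ks_max = 4.0, ks_max_selection = 3.0, max_components = 4L,
    synfind_min_span = 4L, synfind_max_gap = 40L,
    n_perm = 1000L, alpha = 0.05,
    triad_rule = "beat_both", statistic = "mean_ratio",
    seed = 1L
  )
  apply_over <- function(cfg, over, origin) {
    # flatten one level of per-stage sections
    flat <- list()
    for (k in names(over)) {
      if (is.list(over[[k]]) && !is.null(names(over[[k]])))
        flat <- c(flat, over[[k]])
      else flat[[k]] <- over[[k]]
    }
    unknown <- setdiff(names(flat), names(cfg))
    if (length(unknown) > 0)
      stop("unknown config key(s) in ", origin, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    utils::modifyList(cfg, flat)
  }
  if (!is.null(file)) cfg <- apply_over(cfg, yaml::read_yaml(file), file)
  over <- list(...)
  if (length(over) > 0) cfg <- apply_over(cfg, over, "arguments")
  if (cfg$min_span < 2 || cfg$synfind_min_span < 2)
    stop("min_span must be >= 2", call. = FALSE)
  if (cfg$alpha <= 0 || cfg$alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  if (cfg$n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (cfg$ks_max <= 0) stop("ks_max must be > 0", call. = FALSE)
  structure(cfg, class = "analysis_config")
}

#' Run the full analysis chain on a simulated scenario
#'
#' simulate -> synteny (self and cross comparisons) -> depth ratios ->
#' subgenome assignment and fractionation bias -> duplication-mode
#' classification -> Ka/Ks and Ks-mixture dating -> syntelog table and
#' permutation retention test -> expression dominance. When `out_dir` is
#' given, every stage output is written there along with a `manifest.json`
#' recording parameters, seed and file checksums.
#'
#' @param scenario an [evolution_scenario()].
#' @param config an [analysis_config()].
#' @param focal_set optional reference gene ids for the retention test;
#'   default: the reference genes whose 2x lineage retains both ohnolog
#'   copies are sampled to size `focal_size` (emulating a preferentially
#'   retained gene family), deterministically from the config seed.
#' @param focal_size focal set size (default 43).
#' @param out_dir optional output directory.
#' @return a results bundle (list; see components).
#' @export
run_scenario_analysis <- function(scenario = evolution_scenario(),
                                  config = analysis_config(),
                                  focal_set = NULL, focal_size = 43L,
                                  out_dir = NULL) {
  ds <- simulate_dataset(scenario)
  ref <- ds$ref
  l2 <- ds$lineages$lineage2x
  l3 <- ds$lineages$lineage3x

  chain <- function(a, b, hom, min_span = config$min_span, max_gap = config$max_gap)
    chain_blocks(build_anchors(a, b, hom),
                 min_span = min_span, max_gap = max_gap,
                 gap_penalty = config$gap_penalty)

  hom_ref2 <- filter_homology(dataset_homology(ds, "ref", "lineage2x"),
                              config$max_evalue, config$top_n)
  hom_self2 <- filter_homology(dataset_homology(ds, "lineage2x"),
                               config$max_evalue, config$top_n)
  # within-genome pairs ride along so tandem arrays collapse before chaining
  hom_ref2c <- rbind(hom_ref2, hom_self2)
  blocks_ref2 <- chain(ref, l2, hom_ref2c)
  blocks_self2 <- chain(l2, l2, hom_self2)
  blocks_2ref <- chain(l2, ref, hom_ref2c)

  results <- list(dataset = ds, scenario = scenario, config = config,
                  blocks = list(ref_vs_2x = blocks_ref2, self_2x = blocks_self2))

  # syntenic depth ratios
  prof <- function(bl, ga, gb) list(a = compute_depth(bl, ga, "a"),
                                    b = compute_depth(bl, gb, "b"))
  p2 <- prof(blocks_ref2, ref, l2)
  results$depth <- list(ref_vs_2x = summarize_depth_ratio(p2$a, p2$b))

  # fractionation
  asg2 <- assign_subgenomes(ref, blocks_ref2, ploidy = 2L)
  ret2 <- retention_windows(asg2, window = config$window, step = config$step)
  results$fractionation <- list(
    lineage2x = list(assignment = asg2, profile = ret2, bias = summarize_bias(ret2)))

  # duplication modes (2x lineage; the 1x reference plays the outgroup)
  calls2 <- classify_pairs(l2, hom_self2, blocks_self2, blocks_2ref)
  results$duplication <- list(lineage2x = calls2)

  # Ka/Ks on ohnolog (wgd-mode) pairs + mixture dating
  wgd2 <- calls2$calls[calls2$calls$mode == "wgd", c("gene_a", "gene_b")]
  kk2 <- kaks_table(wgd2, l2$cds)
  results$kaks <- list(lineage2x = kk2)
  results$ks_fit <- list()
  ks2 <- kk2$Ks[!is.na(kk2$Ks)]
  if (length(ks2) >= 50)
    results$ks_fit$lineage2x <- fit_ks_mixture(ks2, ks_max = config$ks_max,
                                               max_components = config$max_components)

  if (!is.null(l3)) {
    hom_ref3 <- filter_homology(dataset_homology(ds, "ref", "lineage3x"),
                                config$max_evalue, config$top_n)
    hom_self3 <- filter_homology(dataset_homology(ds, "lineage3x"),
                                 config$max_evalue, config$top_n)
    hom_23 <- filter_homology(dataset_homology(ds, "lineage2x", "lineage3x"),
                              config$max_evalue, config$top_n)
    hom_ref3c <- rbind(hom_ref3, hom_self3)
    blocks_ref3 <- chain(ref, l3, hom_ref3c)
    blocks_self3 <- chain(l3, l3, hom_self3)
    blocks_23 <- chain(l2, l3, rbind(hom_23, hom_self2, hom_self3))
    results$blocks$ref_vs_3x <- blocks_ref3
    results$blocks$self_3x <- blocks_self3
    results$blocks$x2_vs_x3 <- blocks_23

    p3 <- prof(blocks_ref3, ref, l3)
    p23 <- prof(blocks_23, l2, l3)
    results$depth$ref_vs_3x <- summarize_depth_ratio(p3$a, p3$b)
    results$depth$x2_vs_x3 <- summarize_depth_ratio(p23$a, p23$b)

    asg3 <- assign_subgenomes(ref, blocks_ref3, ploidy = 3L)
    ret3 <- retention_windows(asg3, window = config$window, step = config$step)
    results$fractionation$lineage3x <-
      list(assignment = asg3, profile = ret3, bias = summarize_bias(ret3))

    blocks_3ref <- chain(l3, ref, hom_ref3c)
    calls3 <- classify_pairs(l3, hom_self3, blocks_self3, blocks_3ref)
    results$duplication$lineage3x <- calls3
    wgd3 <- calls3$calls[calls3$calls$mode == "wgd", c("gene_a", "gene_b")]
    kk3 <- kaks_table(wgd3, l3$cds)
    results$kaks$lineage3x <- kk3
    ks3 <- kk3$Ks[!is.na(kk3$Ks)]
    if (length(ks3) >= 50)
      results$ks_fit$lineage3x <- assign_ks_peaks(
        fit_ks_mixture(ks3, ks_max = config$ks_max,
                       max_components = config$max_components),
        c("genome-addition", "shared-WGD"))

    # syntelog table over both targets + retention permutation test
    synchain <- function(a, b, hom)
      chain(a, b, hom, min_span = config$synfind_min_span,
            max_gap = config$synfind_max_gap)
    table <- build_syntelog_table(
      ref, list(lineage2x = l2, lineage3x = l3),
      list(lineage2x = synchain(ref, l2, hom_ref2c),
           lineage3x = synchain(ref, l3, hom_ref3c)))
    results$syntelogs <- table
    if (is.null(focal_set)) {
      mat <- syntelog_matrix(table)
      cands <- rownames(mat)[mat[, "lineage2x"] >= 2]
      set.seed(config$seed)
      focal_set <- sample(cands, min(focal_size, length(cands)))
    }
    results$focal_set <- focal_set
    results$retention_test <- permutation_retention_test(
      table, focal_set, "lineage2x", "lineage3x",
      n_perm = config$n_perm, seed = config$seed,
      statistic = config$statistic)
    results$copy_number <- copy_number_summary(table, focal_set, k = 2L)
  }

  # expression dominance (truth-derived ohnolog groups)
  if (!is.null(ds$expression)) {
    g2 <- ohnolog_groups_from_truth(ds, "lineage2x")
    d2 <- dominance_calls(g2, ds$expression, alpha = config$alpha,
                          triad_rule = config$triad_rule)
    results$dominance <- list(lineage2x = list(groups = g2, calls = d2,
                                               summary = summarize_dominance(d2)))
    if (!is.null(l3)) {
      g3 <- ohnolog_groups_from_truth(ds, "lineage3x")
      d3 <- dominance_calls(g3, ds$expression, alpha = config$alpha,
                            triad_rule = config$triad_rule)
      results$dominance$lineage3x <- list(groups = g3, calls = d3,
                                          summary = summarize_dominance(d3))
    }
  }

  results$recovery <- evaluate_recovery(results)
  if (!is.null(out_dir)) write_results(results, out_dir)
  results
}

#' Score analysis results against the simulation truth
#'
#' @param results bundle from [run_scenario_analysis()].
#' @param truth a truth log; defaults to the bundle's own. Supplying a truth
#'   from a different scenario is an error.
#' @return object of class `recovery_report`: depth-ratio agreement,
#'   subgenome label accuracy, per-mode classification precision/recall, Ks
#'   peak errors, retention estimates vs truth, retention-test p and
#'   dominance summaries.
#' @export
evaluate_recovery <- function(results, truth = results$dataset$truth) {
  own <- results$dataset$truth
  if (!identical(sort(truth$genes$id), sort(own$genes$id)))
    stop("truth log does not match the results' scenario", call. = FALSE)
  sc <- results$scenario
  rep <- list()

  rep$depth_ratios <- lapply(results$depth, function(d) d$ratio_label)

  # subgenome label accuracy per lineage
  rep$subgenome_accuracy <- list()
  for (lname in names(results$fractionation)) {
    asg <- results$fractionation[[lname]]$assignment
    tl <- asg$target_gene_labels
    tg <- truth$genes[truth$genes$genome == lname, ]
    truth_lab <- stats::setNames(tg$subgenome, tg$id)
    sel <- tl$gene %in% names(truth_lab)
    got <- tl$label[sel]
    want <- unname(truth_lab[tl$gene[sel]])
    # only base copies carry a meaningful track truth
    base_ids <- tg$id[tg$origin %in% c("wgd", "addition")]
    keep <- tl$gene[sel] %in% base_ids
    rep$subgenome_accuracy[[lname]] <-
      if (sum(keep) > 0) mean(got[keep] == want[keep]) else NA_real_
  }

  # duplication-mode precision/recall (truth events wgd/addition are both
  # polyploidy-derived, expected call "wgd")
  rep$modes <- list()
  for (lname in names(results$duplication)) {
    calls <- results$duplication[[lname]]$calls
    tp <- truth$pairs[truth$pairs$genome == lname, ]
    if (nrow(tp) == 0) next
    expected <- ifelse(tp$event %in% c("wgd", "addition"), "wgd", tp$event)
    tkey <- paste(pmin(tp$gene_a, tp$gene_b), pmax(tp$gene_a, tp$gene_b))
    ckey <- paste(calls$gene_a, calls$gene_b)
    got <- calls$mode[match(tkey, ckey)]
    per_mode <- lapply(.dup_modes, function(m) {
      in_truth <- expected == m
      in_call <- !is.na(got) & got == m
      data.frame(mode = m,
                 n_truth = sum(in_truth),
                 recall = if (sum(in_truth) > 0)
                   sum(in_truth & in_call) / sum(in_truth) else NA_real_,
                 precision = if (sum(calls$mode == m) > 0)
                   sum(in_truth & in_call) / sum(calls$mode == m) else NA_real_)
    })
    rep$modes[[lname]] <- list(
      per_mode = do.call(rbind, per_mode),
      overall_accuracy = mean(got == expected, na.rm = FALSE),
      matched_fraction = mean(!is.na(got)))
  }

  # Ks peak errors against the scenario's event targets
  rep$ks_peaks <- list()
  if (!is.null(results$ks_fit$lineage2x)) {
    comp <- results$ks_fit$lineage2x$components
    rep$ks_peaks$lineage2x <- data.frame(
      target = sc$wgd_ks,
      estimate = comp$mean[which.max(comp$weight)],
      error = comp$mean[which.max(comp$weight)] - sc$wgd_ks)
  }
  if (!is.null(results$ks_fit$lineage3x)) {
    comp <- results$ks_fit$lineage3x$components
    targets <- sort(c(addition = sc$addition_ks, wgd = sc$wgd_ks))
    est <- comp$mean[seq_len(min(nrow(comp), 2))]
    rep$ks_peaks$lineage3x <- data.frame(
      event = names(targets)[seq_along(est)],
      target = unname(targets)[seq_along(est)],
      estimate = est,
      error = est - unname(targets)[seq_along(est)])
  }

  # retention recovery: measured per-track retention vs truth fractions
  rep$retention <- list()
  for (lname in names(results$fractionation)) {
    gw <- results$fractionation[[lname]]$profile$genome_wide
    tr <- truth$retention[truth$retention$genome == lname, ]
    m <- merge(gw, tr[, c("subgenome", "loss_rate", "retained_fraction")],
               by.x = "track", by.y = "subgenome")
    m$error_pct <- m$retained_pct_all - 100 * m$retained_fraction
    rep$retention[[lname]] <- m
  }

  if (!is.null(results$retention_test))
    rep$retention_test_p <- results$retention_test$p_corrected
  if (!is.null(results$dominance))
    rep$dominance <- lapply(results$dominance, `[[`, "summary")

  structure(rep, class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n  depth ratios:",
      paste(names(x$depth_ratios), unlist(x$depth_ratios), sep = "=", collapse = ", "),
      "\n  subgenome accuracy:",
      paste(names(x$subgenome_accuracy),
            sprintf("%.3f", unlist(x$subgenome_accuracy)), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a results bundle to a directory with a manifest
#'
#' @param results bundle from [run_scenario_analysis()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_dataset(results$dataset, file.path(out_dir, "dataset"))
  for (nm in names(results$blocks))
    write_blocks(results$blocks[[nm]], file.path(out_dir, paste0("blocks_", nm, ".tsv")))
  for (nm in names(results$fractionation)) {
    utils::write.table(results$fractionation[[nm]]$profile$windows,
                       file.path(out_dir, paste0("retention_windows_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(results$fractionation[[nm]]$bias,
                         file.path(out_dir, paste0("bias_", nm, ".json")),
                         dataframe = "columns", auto_unbox = TRUE, digits = NA)
  }
  for (nm in names(results$duplication))
    write_duplication_calls(results$duplication[[nm]],
                            file.path(out_dir, paste0("duplication_", nm, ".tsv")))
  for (nm in names(results$kaks))
    utils::write.table(results$kaks[[nm]],
                       file.path(out_dir, paste0("kaks_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(results$ks_fit))
    jsonlite::write_json(unclass(results$ks_fit[[nm]]),
                         file.path(out_dir, paste0("ks_fit_", nm, ".json")),
                         dataframe = "columns", auto_unbox = TRUE, digits = NA)
  if (!is.null(results$syntelogs))
    write_syntelog_table(results$syntelogs, file.path(out_dir, "syntelog_table.tsv"))
  if (!is.null(results$retention_test))
    jsonlite::write_json(unclass(results$retention_test),
                         file.path(out_dir, "retention_test.json"),
                         auto_unbox = TRUE, digits = NA)
  for (nm in names(results$dominance))
    utils::write.table(results$dominance[[nm]]$summary,
                       file.path(out_dir, paste0("dominance_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  manifest <- list(
    package = "syntevo",
    seed = results$scenario$seed,
    scenario = unclass(results$scenario),
    config = unclass(results$config),
    files = data.frame(
      path = files,
      md5 = unname(tools::md5sum(file.path(out_dir, files))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out_dir)
}
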