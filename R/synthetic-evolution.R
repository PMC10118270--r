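#' Define a polyploid-evolution scenario
#'
#' The scenario fixes the study conditions the simulator emulates: one shared
#' whole-genome duplication (2x) producing a tetraploid-derived lineage, an
#' optional additional genome merger (+1x) producing a hexaploid-derived
#' lineage, per-subgenome biased gene loss, single-gene duplications of four
#' modes, codon divergence clustered around event-specific Ks targets, and
#' subgenome-biased expression with replicated samples.
#'
#' Default loss rates mirror the retention contrast reported for real
#' Cleomaceae subgenomes (least-fractionated track ~77% vs ~53% in the 2x
#' lineage; 64/44/28% across the three 3x tracks). In the 3x lineage the
#' *added* subgenome is, by convention, the least-fractionated track and is
#' labelled LF.
#'
#' @param n_chromosomes chromosomes in the ancestral genome.
#' @param genes_per_chromosome genes per ancestral chromosome.
#' @param codons_per_gene codons per coding sequence (incl. start codon).
#' @param wgd simulate the shared whole-genome duplication.
#' @param wgd_ks target synonymous divergence (Ks) between the two WGD
#'   subgenome copies.
#' @param addition simulate the +1x genome addition (3x lineage).
#' @param addition_ks target Ks between the added subgenome and either WGD
#'   subgenome; must be >= `wgd_ks / 2` (additive branch model).
#' @param loss_rates_2x named probabilities of gene loss per subgenome track
#'   of the 2x lineage (`LF`, `MF`).
#' @param loss_rates_3x named loss probabilities for the 3x lineage
#'   (`LF` = added track, `MF1`, `MF2`).
#' @param single_gene_rates named per-gene probabilities of spawning a
#'   duplicate of each mode (`tandem`, `proximal`, `transposed`, `dispersed`).
#' @param sgd_ks target Ks between a single-gene duplicate and its source.
#' @param omega Ka/Ks ratio used when mutating sequences.
#' @param dominance_effect multiplicative TPM factor (>= 1) applied to genes
#'   of LF subgenomes.
#' @param samples sample labels for the expression matrix.
#' @param replicates replicates per sample (default 3).
#' @param seed integer seed; every stochastic stage derives its stream from it.
#' @return an object of class `evolution_scenario`.
#' @export
evolution_scenario <- function(n_chromosomes = 5L,
                               genes_per_chromosome = 200L,
                               codons_per_gene = 200L,
                               wgd = TRUE, wgd_ks = 0.5,
                               addition = TRUE, addition_ks = 0.25,
                               loss_rates_2x = c(LF = 0.23, MF = 0.47),
                               loss_rates_3x = c(LF = 0.36, MF1 = 0.56, MF2 = 0.72),
                               single_gene_rates = c(tandem = 0.03, proximal = 0.03,
                                                     transposed = 0.03, dispersed = 0.03),
                               sgd_ks = 0.1,
                               omega = 0.2,
                               dominance_effect = 2,
                               samples = c("Leaf", "Stem", "Root"),
                               replicates = 3L,
                               seed = 1L) {
  sc <- list(n_chromosomes = as.integer(n_chromosomes),
             genes_per_chromosome = as.integer(genes_per_chromosome),
             codons_per_gene = as.integer(codons_per_gene),
             wgd = isTRUE(wgd), wgd_ks = wgd_ks,
             addition = isTRUE(addition), addition_ks = addition_ks,
             loss_rates_2x = loss_rates_2x, loss_rates_3x = loss_rates_3x,
             single_gene_rates = single_gene_rates, sgd_ks = sgd_ks,
             omega = omega, dominance_effect = dominance_effect,
             samples = samples, replicates = as.integer(replicates),
             seed = as.integer(seed))
  stopifnot(sc$n_chromosomes >= 1, sc$genes_per_chromosome >= 1,
            sc$codons_per_gene >= 2)
  if (!all(c("LF", "MF") %in% names(sc$loss_rates_2x)))
    stop("loss_rates_2x needs named entries LF and MF", call. = FALSE)
  if (!all(c("LF", "MF1", "MF2") %in% names(sc$loss_rates_3x)))
    stop("loss_rates_3x needs named entries LF, MF1, MF2", call. = FALSE)
  probs <- c(sc$loss_rates_2x, sc$loss_rates_3x, sc$single_gene_rates)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0,1]", call. = FALSE)
  if (sc$wgd_ks < 0 || sc$addition_ks < 0 || sc$sgd_ks < 0)
    stop("Ks targets must be >= 0", call. = FALSE)
  if (sc$addition && sc$wgd && sc$addition_ks < sc$wgd_ks / 2)
    stop("addition_ks must be >= wgd_ks/2 under the additive branch model",
         call. = FALSE)
  if (sc$dominance_effect < 1) stop("dominance_effect must be >= 1", call. = FALSE)
  if (!all(names(sc$single_gene_rates) %in%
           c("tandem", "proximal", "transposed", "dispersed")))
    stop("unknown single-gene duplication mode", call. = FALSE)
  class(sc) <- "evolution_scenario"
  sc
}

#' @export
print.evolution_scenario <- function(x, ...) {
  cat("<evolution_scenario>", x$n_chromosomes, "x", x$genes_per_chromosome,
      "genes;", if (x$wgd) sprintf("WGD Ks=%.2f;", x$wgd_ks) else "no WGD;",
      if (x$addition) sprintf("+1x Ks=%.2f;", x$addition_ks) else "no addition;",
      "seed", x$seed, "\n")
  invisible(x)
}

# 61 sense codons for random CDS generation
sense_codons <- function() {
  tab <- codon_tables()
  tab$codons[!tab$is_stop]
}

#' Simulate the ancestral genome
#'
#' Genes are laid out at regular coordinates along each chromosome; coding
#' sequences are random in-frame sequences starting with ATG and free of
#' internal stop codons. Deterministic given the scenario seed.
#'
#' @param scenario an [evolution_scenario()].
#' @return a `genome` named `"ancestor"` with CDS attached.
#' @export
simulate_ancestor <- function(scenario) {
  set.seed(scenario$seed)
  nch <- scenario$n_chromosomes
  npc <- scenario$genes_per_chromosome
  len <- 3L * scenario$codons_per_gene
  ids <- as.vector(vapply(seq_len(nch), function(c)
    sprintf("anc_c%02d_g%04d", c, seq_len(npc)), character(npc)))
  genes <- data.frame(
    id = ids,
    chromosome = rep(sprintf("chr%02d", seq_len(nch)), each = npc),
    start = rep((seq_len(npc) - 1L) * 2000L + 1L, times = nch),
    end = rep((seq_len(npc) - 1L) * 2000L + len, times = nch),
    strand = "+"
  )
  sense <- sense_codons()
  cds <- vapply(seq_along(ids), function(i) {
    paste0("ATG", paste(sample(sense, scenario$codons_per_gene - 1L, replace = TRUE),
                        collapse = ""))
  }, character(1))
  names(cds) <- ids
  new_genome("ancestor", genes, cds = cds)
}

# internal record of one lineage while it is being evolved: a data.frame of
# gene slots with fractional order keys per chromosome
.track_letters <- c(LF = "A", MF = "B", MF1 = "B", MF2 = "C")

#' Evolve polyploid lineages from an ancestor
#'
#' Applies the scenario's history: the 2x lineage carries two subgenome
#' copies (LF/MF) of every ancestral chromosome; the 3x lineage carries the
#' two WGD copies (MF1/MF2) plus the added, least-fractionated copy (LF).
#' Each subgenome copy loses each gene independently at its track's loss
#' rate; single-gene duplications are then planted per mode. Sequences are
#' not yet mutated (see [evolve_cds()]). The truth log records every gene's
#' provenance and every planted duplicate pair with its event and Ks target.
#'
#' @param ancestor genome from [simulate_ancestor()].
#' @param scenario the same [evolution_scenario()].
#' @return a `simulated_dataset`: list with `ref` (the 1x reference, an
#'   undisturbed copy of the ancestral gene order), `lineages` (named list of
#'   `genome`s), `truth` (truth log) and `scenario`.
#' @export
evolve_polyploid_lineages <- function(ancestor, scenario) {
  set.seed(scenario$seed + 1L)
  if (!scenario$wgd) stop("scenario without WGD has no polyploid lineage", call. = FALSE)

  lineage_plan <- list()
  lineage_plan$lineage2x <- scenario$loss_rates_2x
  if (scenario$addition) lineage_plan$lineage3x <- scenario$loss_rates_3x

  anc <- ancestor$genes
  truth_genes <- list()
  truth_pairs <- list()
  retention <- list()
  lineages <- list()

  for (lname in names(lineage_plan)) {
    rates <- lineage_plan[[lname]]
    if (all(rates >= 1)) stop("all loss rates are 1: empty genome", call. = FALSE)
    short <- sub("lineage", "", lname)  # "2x" / "3x"
    slots <- list()
    for (track in names(rates)) {
      keep <- stats::runif(nrow(anc)) >= rates[[track]]
      g <- anc[keep, , drop = FALSE]
      if (nrow(g) == 0) next
      # order key: ancestral gene index along its chromosome
      anc_key <- stats::ave(seq_len(nrow(anc)), anc$chromosome, FUN = seq_along)
      names(anc_key) <- anc$id
      slots[[track]] <- data.frame(
        id = sprintf("g%s_%s_%s", short, track, g$id),
        chromosome = paste0(g$chromosome, .track_letters[[track]]),
        key = as.numeric(anc_key[g$id]),
        ancestral_id = g$id,
        subgenome = track,
        origin = if (track == "LF" && lname == "lineage3x") "addition" else "wgd",
        source = NA_character_
      )
    }

    genes <- do.call(rbind, slots)
    rownames(genes) <- NULL

    # single-gene duplications, planted per mode on surviving base genes
    planted <- plant_single_gene_duplications(genes, scenario, short)
    genes <- planted$genes

    # WGD / addition ohnolog pairs among surviving base copies
    base <- genes[genes$origin %in% c("wgd", "addition"), ]
    by_anc <- split(base$id, base$ancestral_id)
    track_of <- stats::setNames(base$subgenome, base$id)
    for (ids in by_anc) {
      if (length(ids) < 2) next
      cmb <- utils::combn(sort(ids), 2)
      for (k in seq_len(ncol(cmb))) {
        ta <- track_of[[cmb[1, k]]]; tb <- track_of[[cmb[2, k]]]
        ev <- if ("LF" %in% c(ta, tb) && lname == "lineage3x") "addition" else "wgd"
        ks <- if (ev == "addition") scenario$addition_ks else scenario$wgd_ks
        truth_pairs[[length(truth_pairs) + 1L]] <- data.frame(
          genome = lname, gene_a = cmb[1, k], gene_b = cmb[2, k],
          event = ev, ks_target = ks)
      }
    }
    sgd_pairs <- planted$pairs
    if (nrow(sgd_pairs) > 0) {
      # prune pairs whose members were deleted by later flank losses
      keep <- sgd_pairs$gene_a %in% genes$id & sgd_pairs$gene_b %in% genes$id
      sgd_pairs <- sgd_pairs[keep, , drop = FALSE]
      if (nrow(sgd_pairs) > 0)
        truth_pairs[[length(truth_pairs) + 1L]] <- data.frame(
          genome = lname,
          gene_a = pmin(sgd_pairs$gene_a, sgd_pairs$gene_b),
          gene_b = pmax(sgd_pairs$gene_a, sgd_pairs$gene_b),
          event = sgd_pairs$event, ks_target = scenario$sgd_ks)
    }

    # realized retention per track (base copies surviving everything)
    for (track in names(rates)) {
      n_kept <- sum(base$subgenome == track)
      retention[[length(retention) + 1L]] <- data.frame(
        genome = lname, subgenome = track, loss_rate = rates[[track]],
        n_ancestral = nrow(anc), n_retained = n_kept,
        retained_fraction = n_kept / nrow(anc))
    }

    # materialize the genome: order by (chromosome, key), regular coordinates
    genes <- genes[order(genes$chromosome, genes$key), , drop = FALSE]
    pos <- as.integer(stats::ave(seq_len(nrow(genes)), genes$chromosome, FUN = seq_along))
    len <- 3L * scenario$codons_per_gene
    gtab <- data.frame(id = genes$id, chromosome = genes$chromosome,
                       start = (pos - 1L) * 2000L + 1L,
                       end = (pos - 1L) * 2000L + len, strand = "+")
    lineages[[lname]] <- new_genome(lname, gtab)
    truth_genes[[lname]] <- data.frame(
      genome = lname, id = genes$id, ancestral_id = genes$ancestral_id,
      subgenome = genes$subgenome, origin = genes$origin, source = genes$source)
  }

  truth_genes$ref <- data.frame(
    genome = "ref", id = anc$id, ancestral_id = anc$id,
    subgenome = "outgroup", origin = "ancestral", source = NA_character_)

  ref <- new_genome("ref", ancestor$genes[, c("id", "chromosome", "start", "end", "strand")],
                    cds = ancestor$cds)
  structure(list(
    ref = ref,
    lineages = lineages,
    truth = list(genes = do.call(rbind, c(truth_genes, list(make.row.names = FALSE))),
                 pairs = if (length(truth_pairs) > 0)
                   do.call(rbind, c(truth_pairs, list(make.row.names = FALSE)))
                 else data.frame(genome = character(), gene_a = character(),
                                 gene_b = character(), event = character(),
                                 ks_target = numeric()),
                 retention = do.call(rbind, c(retention, list(make.row.names = FALSE)))),
    scenario = scenario
  ), class = "simulated_dataset")
}

# plant tandem/proximal/transposed/dispersed duplicates on a lineage's gene
# slot table (columns id, chromosome, key, ancestral_id, subgenome, origin,
# source). Keys are fractional order positions within a chromosome; insertion
# keys are chosen against the surviving gene order so planted rank distances
# are exact (tandem = 1, proximal = 2..10) at planting time.
plant_single_gene_duplications <- function(genes, scenario, short) {
  rates <- scenario$single_gene_rates
  chroms <- unique(genes$chromosome)
  counter <- 0L
  pairs <- list()
  for (mode in c("tandem", "proximal", "transposed", "dispersed")) {
    rate <- rates[[mode]]
    if (is.null(rate) || rate <= 0) next
    base_idx <- which(genes$origin %in% c("wgd", "addition"))
    hit <- base_idx[stats::runif(length(base_idx)) < rate]
    for (i in hit) {
      if (is.na(genes$id[i])) next  # deleted meanwhile by a dispersed event
      counter <- counter + 1L
      src <- genes[i, ]
      copy_id <- sprintf("g%s_%s%04d_%s", short, substr(mode, 1, 2), counter,
                         src$ancestral_id)
      if (mode == "tandem") {
        new_row <- src
        new_row$id <- copy_id
        new_row$key <- src$key + 1e-6  # immediately after the source
        new_row$origin <- mode; new_row$source <- src$id
        genes <- rbind(genes, new_row)
        pairs[[length(pairs) + 1L]] <- data.frame(
          gene_a = src$id, gene_b = copy_id, event = mode)
      } else if (mode == "proximal") {
        # insert at a realized rank distance of 2..10 within the current order
        live <- which(genes$chromosome == src$chromosome & !is.na(genes$id))
        live <- live[order(genes$key[live])]
        p <- match(i, live)
        g <- sample(2:10, 1)
        n_live <- length(live)
        key <- NULL
        for (dir in sample(c(1L, -1L))) {
          j1 <- p + dir * (g - 1L)  # last gene between source and insertion
          j2 <- p + dir * g         # first gene beyond the insertion point
          if (j1 < 1 || j1 > n_live) next  # not enough room in this direction
          k1 <- genes$key[live[j1]]
          k2 <- if (j2 >= 1 && j2 <= n_live) genes$key[live[j2]] else k1 + dir
          key <- (k1 + k2) / 2
          break
        }
        if (is.null(key)) next  # no room on either side; event dropped
        new_row <- src
        new_row$id <- copy_id
        new_row$key <- key
        new_row$origin <- mode; new_row$source <- src$id
        genes <- rbind(genes, new_row)
        pairs[[length(pairs) + 1L]] <- data.frame(
          gene_a = src$id, gene_b = copy_id, event = mode)
      } else if (mode == "transposed") {
        other <- setdiff(chroms, src$chromosome)
        if (length(other) == 0) next
        tchrom <- if (length(other) == 1) other else sample(other, 1)
        new_row <- src
        new_row$id <- copy_id
        new_row$chromosome <- tchrom
        new_row$key <- stats::runif(1, 1, scenario$genes_per_chromosome)
        new_row$origin <- mode; new_row$source <- src$id
        genes <- rbind(genes, new_row)
        pairs[[length(pairs) + 1L]] <- data.frame(
          gene_a = src$id, gene_b = copy_id, event = mode)
      } else {
        # dispersed: a duplication with later loss of all positional context.
        # The ancestral locus is lost and BOTH resulting copies sit at random
        # loci in foreign context (with the nearest surviving ancestral
        # neighbour on each side of each insertion deleted), so neither
        # member retains an ancestral locus - the defining residue class.
        other <- setdiff(chroms, src$chromosome)
        if (length(other) == 0) next
        twin_ids <- c(sprintf("g%s_di%04da_%s", short, counter, src$ancestral_id),
                      copy_id)
        new_rows <- list()
        for (part in 1:2) {
          row <- src
          tchrom <- if (length(other) == 1) other else sample(other, 1)
          row$chromosome <- tchrom
          row$key <- stats::runif(1, 1, scenario$genes_per_chromosome)
          row$id <- twin_ids[part]
          row$origin <- "dispersed"
          row$source <- src$id
          on_chrom <- which(genes$chromosome == tchrom &
                              genes$origin %in% c("wgd", "addition") &
                              !is.na(genes$id))
          if (length(on_chrom) > 0) {
            dk <- genes$key[on_chrom] - row$key
            left <- on_chrom[dk < 0]
            right <- on_chrom[dk > 0]
            kill <- c(if (length(left) > 0) left[which.max(genes$key[left])],
                      if (length(right) > 0) right[which.min(genes$key[right])])
            genes$id[kill] <- NA_character_
          }
          new_rows[[part]] <- row
        }
        genes$id[i] <- NA_character_  # the ancestral locus is lost
        genes <- rbind(genes, new_rows[[1]], new_rows[[2]])
        pairs[[length(pairs) + 1L]] <- data.frame(
          gene_a = twin_ids[1], gene_b = twin_ids[2], event = mode)
      }
    }
    genes <- genes[!is.na(genes$id), , drop = FALSE]
  }
  list(genes = genes[!is.na(genes$id), , drop = FALSE],
       pairs = if (length(pairs) > 0) do.call(rbind, pairs)
         else data.frame(gene_a = character(), gene_b = character(),
                         event = character()))
}

# per-codon single-mutation option tables for the simulator: target codon
# indices of synonymous / nonsynonymous (non-stop) neighbours
mutation_options <- function() {
  if (!is.null(.codon_cache$opts)) return(.codon_cache$opts)
  tab <- codon_tables()
  syn <- lapply(tab$neighbours, function(nb) nb$to[nb$syn])
  non <- lapply(tab$neighbours, function(nb) nb$to[!nb$syn & !nb$to_stop])
  .codon_cache$opts <- list(syn = syn, n_syn = lengths(syn),
                            non = non, n_non = lengths(non))
  .codon_cache$opts
}

# Apply Poisson numbers of synonymous / nonsynonymous substitutions to a
# codon-index vector, choosing sites uniformly among the current sequence's
# eligible single-nucleotide changes (equal-rate, Jukes-Cantor-like scheme;
# no transition/transversion bias). The start codon is left untouched.
mutate_codons <- function(idx, ks, omega) {
  tab <- codon_tables()
  opts <- mutation_options()
  if (ks > 1.5) {
    warning("branch Ks ", signif(ks, 3),
            " approaches synonymous saturation; capped at 1.5", call. = FALSE)
    ks <- 1.5
  }
  len <- length(idx)
  if (len < 2 || ks <= 0) {
    n_syn_ev <- 0L; n_non_ev <- 0L
  } else {
    S <- sum(tab$syn_sites[idx[-1]])
    N <- 3 * (len - 1) - S
    n_syn_ev <- stats::rpois(1, ks * S)
    n_non_ev <- stats::rpois(1, omega * ks * N)
  }
  if (n_syn_ev + n_non_ev == 0) return(idx)
  events <- sample(rep(c(TRUE, FALSE), c(n_syn_ev, n_non_ev)))
  for (syn in events) {
    w <- if (syn) opts$n_syn[idx] else opts$n_non[idx]
    w[1] <- 0
    if (sum(w) == 0) next
    pos <- sample.int(len, 1L, prob = w)
    targets <- if (syn) opts$syn[[idx[pos]]] else opts$non[[idx[pos]]]
    idx[pos] <- if (length(targets) == 1L) targets else sample(targets, 1L)
  }
  idx
}

#' Mutate coding sequences along the simulated history
#'
#' Each subgenome copy receives its own branch of synonymous divergence under
#' an additive model: the two WGD tracks each carry `wgd_ks / 2`, and the
#' added 3x track carries `addition_ks - wgd_ks / 2`, so that WGD ohnolog
#' pairs have expected pairwise Ks `wgd_ks` and pairs involving the added
#' subgenome have expected Ks `addition_ks`. Single-gene duplicates diverge
#' from their source by `sgd_ks`. Substitution counts are Poisson with mean
#' Ks x synonymous sites (nonsynonymous: omega x Ks x nonsynonymous sites).
#'
#' @param dataset a `simulated_dataset` from [evolve_polyploid_lineages()].
#' @param scenario the scenario (defaults to the dataset's own).
#' @return the dataset with CDS attached to every lineage genome.
#' @export
evolve_cds <- function(dataset, scenario = dataset$scenario) {
  set.seed(scenario$seed + 2L)
  anc_cds_idx <- lapply(dataset$ref$cds, cds_to_codons)
  branch <- list(
    lineage2x = c(LF = scenario$wgd_ks / 2, MF = scenario$wgd_ks / 2),
    lineage3x = c(LF = scenario$addition_ks - scenario$wgd_ks / 2,
                  MF1 = scenario$wgd_ks / 2, MF2 = scenario$wgd_ks / 2)
  )
  truth <- dataset$truth$genes
  for (lname in names(dataset$lineages)) {
    genome <- dataset$lineages[[lname]]
    tg <- truth[truth$genome == lname, ]
    tg <- tg[match(genome$genes$id, tg$id), ]
    cds_idx <- vector("list", nrow(tg))
    names(cds_idx) <- tg$id
    is_base <- tg$origin %in% c("wgd", "addition")
    for (i in which(is_base)) {
      b <- branch[[lname]][[tg$subgenome[i]]]
      cds_idx[[i]] <- mutate_codons(anc_cds_idx[[tg$ancestral_id[i]]],
                                    ks = b, omega = scenario$omega)
    }
    # dispersed twins lost their source gene; reconstruct its branch state
    # once per source so the twins share it and diverge by sgd_ks pairwise
    lost_src_state <- list()
    for (i in which(!is_base)) {
      src <- tg$source[i]
      src_idx <- cds_idx[[src]]
      if (is.null(src_idx)) {
        if (is.null(lost_src_state[[src]])) {
          b <- branch[[lname]][[tg$subgenome[i]]]
          lost_src_state[[src]] <- mutate_codons(anc_cds_idx[[tg$ancestral_id[i]]],
                                                 ks = b, omega = scenario$omega)
        }
        src_idx <- lost_src_state[[src]]
      }
      half <- tg$origin[i] == "dispersed" && !tg$source[i] %in% tg$id
      cds_idx[[i]] <- mutate_codons(src_idx,
                                    ks = if (half) scenario$sgd_ks / 2
                                         else scenario$sgd_ks,
                                    omega = scenario$omega)
    }
    cds <- vapply(cds_idx, codons_to_cds, character(1))
    dataset$lineages[[lname]] <- new_genome(lname, genome$genes[, 1:5], cds = cds)
  }
  dataset
}

#' Simulate subgenome-biased replicate expression
#'
#' Per gene, a log-normal expression model: an ancestral-gene-level mean
#' (shared by all copies of one ancestral gene), a copy-level deviation, a
#' gene-by-sample shift, and replicate noise. Genes on LF-labelled subgenomes
#' have their means multiplied by `dominance_effect`. TPM values for all
#' lineage genes, `replicates` per sample; deterministic given the seed.
#'
#' @inheritParams evolve_cds
#' @param sdlog_gene between-ancestral-gene spread of log mean TPM.
#' @param sdlog_copy copy-level deviation between ohnolog copies.
#' @param sdlog_sample gene-by-sample shift.
#' @param sdlog_rep replicate noise.
#' @param base_tpm median TPM of the genome.
#' @return the dataset with an `expression` matrix attached.
#' @export
simulate_expression <- function(dataset, scenario = dataset$scenario,
                                sdlog_gene = 1.5, sdlog_copy = 0.3,
                                sdlog_sample = 0.3, sdlog_rep = 0.2,
                                base_tpm = 20) {
  set.seed(scenario$seed + 3L)
  truth <- dataset$truth$genes
  tg <- truth[truth$genome != "ref", ]
  anc_ids <- sort(unique(tg$ancestral_id))
  mu_anc <- stats::setNames(stats::rnorm(length(anc_ids), log(base_tpm), sdlog_gene),
                            anc_ids)
  eta <- stats::rnorm(nrow(tg), 0, sdlog_copy)
  mu <- mu_anc[tg$ancestral_id] + eta +
    ifelse(tg$subgenome == "LF", log(scenario$dominance_effect), 0)
  samples <- scenario$samples
  reps <- scenario$replicates
  delta <- matrix(stats::rnorm(nrow(tg) * length(samples), 0, sdlog_sample),
                  nrow = nrow(tg))
  vals <- matrix(0, nrow(tg), length(samples) * reps)
  colnames(vals) <- as.vector(t(outer(samples, seq_len(reps),
                                      function(s, k) paste0(s, "_r", k))))
  for (si in seq_along(samples)) {
    for (k in seq_len(reps)) {
      vals[, (si - 1L) * reps + k] <-
        exp(mu + delta[, si] + stats::rnorm(nrow(tg), 0, sdlog_rep))
    }
  }
  rownames(vals) <- tg$id
  dataset$expression <- new_expression_matrix(vals)
  dataset
}

#' Run the full simulator
#'
#' Convenience wrapper: [simulate_ancestor()], [evolve_polyploid_lineages()],
#' [evolve_cds()] and [simulate_expression()] in sequence.
#'
#' @param scenario an [evolution_scenario()].
#' @param sequences mutate coding sequences (skip to save time when only gene
#'   orders are needed).
#' @param expression simulate the expression matrix.
#' @return a `simulated_dataset`.
#' @export
simulate_dataset <- function(scenario = evolution_scenario(),
                             sequences = TRUE, expression = TRUE) {
  anc <- simulate_ancestor(scenario)
  ds <- evolve_polyploid_lineages(anc, scenario)
  if (sequences) ds <- evolve_cds(ds)
  if (expression) ds <- simulate_expression(ds)
  ds
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("<simulated_dataset> ref:", n_genes(x$ref), "genes;",
      paste(vapply(names(x$lineages), function(n)
        paste0(n, ": ", n_genes(x$lineages[[n]])), character(1)), collapse = "; "),
      "\n")
  invisible(x)
}

#' Exact homology table of a simulated dataset
#'
#' All gene pairs sharing an ancestral id between (or within) the named
#' genomes, as a homology table with nominal e-values/bitscores. This is the
#' simulator's stand-in for an all-versus-all protein search: homology is
#' exact by construction.
#'
#' @param dataset a `simulated_dataset`.
#' @param genome_x,genome_y genome names (`"ref"` or lineage names); equal
#'   names give within-genome homology (self-pairs excluded).
#' @return data.frame `gene_a`, `gene_b`, `evalue`, `bitscore`.
#' @export
dataset_homology <- function(dataset, genome_x, genome_y = genome_x) {
  tg <- dataset$truth$genes
  gx <- tg[tg$genome == genome_x, c("id", "ancestral_id")]
  gy <- tg[tg$genome == genome_y, c("id", "ancestral_id")]
  m <- merge(gx, gy, by = "ancestral_id", suffixes = c("_x", "_y"))
  m <- m[m$id_x != m$id_y, , drop = FALSE]
  if (genome_x == genome_y) {
    a <- pmin(m$id_x, m$id_y); b <- pmax(m$id_x, m$id_y)
    m <- data.frame(gene_a = a, gene_b = b)
    m <- m[!duplicated(m), , drop = FALSE]
  } else {
    m <- data.frame(gene_a = m$id_x, gene_b = m$id_y)
  }
  if (nrow(m) == 0)
    return(data.frame(gene_a = character(), gene_b = character(),
                      evalue = numeric(), bitscore = numeric()))
  out <- data.frame(gene_a = m$gene_a, gene_b = m$gene_b,
                    evalue = 1e-50, bitscore = 300)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a simulated dataset to a directory of standard-format files
#'
#' Emits `ref.gff3` / `ref.cds.fasta`, per-lineage GFF3 + CDS FASTA, a
#' combined `homology.tsv` (within- and between-genome pairs), an
#' `expression.tsv`, the `truth.json` log and the `scenario.yaml`.
#'
#' @param dataset a `simulated_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_models(dataset$ref, file.path(dir, "ref.gff3"))
  if (!is.null(dataset$ref$cds)) write_cds(dataset$ref, file.path(dir, "ref.cds.fasta"))
  for (lname in names(dataset$lineages)) {
    g <- dataset$lineages[[lname]]
    write_gene_models(g, file.path(dir, paste0(lname, ".gff3")))
    if (!is.null(g$cds)) write_cds(g, file.path(dir, paste0(lname, ".cds.fasta")))
  }
  gnames <- c("ref", names(dataset$lineages))
  hom <- list()
  for (i in seq_along(gnames)) for (j in i:length(gnames))
    hom[[paste(i, j)]] <- dataset_homology(dataset, gnames[i], gnames[j])
  write_homology(do.call(rbind, hom), file.path(dir, "homology.tsv"))
  if (!is.null(dataset$expression))
    write_expression(dataset$expression, file.path(dir, "expression.tsv"))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", na = "null")
  yaml::write_yaml(unclass(dataset$scenario), file.path(dir, "scenario.yaml"))
  invisible(dir)
}
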