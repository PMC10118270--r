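---
title: "Inferring polyploid genome evolution with syntevo: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring polyploid genome evolution with syntevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntevo)
```

# The problem

After a whole-genome duplication (WGD) or a hybrid genome merger, a plant
genome carries two or three *subgenomes* — complete ancestral gene orders
layered on top of each other. Over time most duplicated genes are lost
again (fractionation), usually unequally between subgenomes, while a
minority of duplicates — often dosage-sensitive pathway genes — are
preferentially retained. `syntevo` infers this history from three data
layers: gene order (GFF3 gene models), coding sequence (FASTA), and
replicate expression (TPM tables). Every inference is exercised against a
forward simulator whose scenario *is* the ground truth.

All positional reasoning operates on the **gene-order rank** (dense
0-based index along each chromosome), not on base pairs: the window rules
of the field ("adjacent", "separated by up to 10 genes", 100-gene
retention windows, 4-gene minimum blocks) are all order-based. GFF3
coordinates stay 1-based inclusive and are used only for reporting; block
spans are reported 0-based half-open and labelled as such.

# The forward simulator

`evolution_scenario()` fixes the study conditions; its defaults are the
conditions every recovery experiment and the acceptance script use:

| parameter | default | meaning |
|---|---|---|
| `n_chromosomes` × `genes_per_chromosome` | 5 × 200 | 1,000 ancestral genes — large enough for ±1 pp retention estimates, small enough for seconds-scale runs |
| `codons_per_gene` | 200 | typical plant CDS length (~600 bp) |
| `wgd_ks` | 0.5 | synonymous divergence between the two WGD subgenome copies |
| `addition_ks` | 0.25 | divergence between the added (+1x) subgenome and either WGD copy |
| `loss_rates_2x` | LF 0.23, MF 0.47 | per-copy loss probabilities chosen to mirror the ~77%/53% retention contrast reported for real tetraploid-derived Cleomaceae subgenomes |
| `loss_rates_3x` | LF 0.36, MF1 0.56, MF2 0.72 | mirroring the ~64%/44%/28% three-track contrast |
| `single_gene_rates` | 0.03 each | tandem, proximal, transposed, dispersed duplication probabilities per surviving gene |
| `sgd_ks` | 0.1 | divergence of a single-gene duplicate from its source ("low divergence", so mode classification is tested on position, not sequence) |
| `omega` | 0.2 | Ka/Ks used while mutating — typical purifying selection |
| `dominance_effect` | 2 | multiplicative TPM advantage of LF-subgenome genes |
| `replicates` | 3 | replicates per expression sample |

Sequence divergence uses an **additive branch model**: each subgenome copy
carries its own branch so that expected pairwise Ks between the two WGD
tracks is `wgd_ks` and between the added track and either WGD track is
`addition_ks` (this requires `addition_ks >= wgd_ks / 2`; the constructor
enforces it). Substitution counts are Poisson with mean Ks × synonymous
sites (nonsynonymous: `omega` × Ks × nonsynonymous sites), placed
uniformly over the current sequence's synonymous (or nonsynonymous,
stop-avoiding) single-nucleotide options — a Jukes–Cantor-like equal-rate
scheme with no transition/transversion bias, deliberately matched to the
NG86 estimator used downstream. Start codons are left untouched. Branches
with Ks > 1.5 are capped with a warning (pairwise Ks beyond ~3 approaches
synonymous saturation). On simulated pairs the NG86 estimate is unbiased:
200 pairs of 300 codons at pair Ks 0.5 average 0.508 (sd 0.07).

Two simulator behaviours deserve explanation:

* **Dispersed duplication.** Tandem, proximal and transposed modes have
  mechanistic definitions; "dispersed" is the residual class — pairs with
  no surviving positional context. Planting a residual class requires care:
  if the duplicate is simply copied to a random locus while the source
  stays put, the resulting pair has exactly one member at an ancestral
  locus and is, by definition, *transposed*. The simulator therefore
  models a dispersed event as duplication **with loss of the ancestral
  locus**: the source locus is deleted and both resulting copies are
  inserted at random positions on other chromosomes, each insertion
  deleting its nearest surviving ancestral neighbour on either side so no
  collinear context survives. A side effect is that the realized retention
  of the default scenario (~68%/45%) sits a few points below the raw loss
  complements (77%/53%); experiments that target retention itself run with
  single-gene rates at zero, where realized retention equals the binomial
  expectation exactly.

* **Determinism.** Each stage (ancestor, lineages, sequences, expression)
  seeds its own stream derived from the scenario seed by a fixed small
  offset, so stages are reproducible independently of which earlier stages
  were re-run, and `write_dataset()` output is byte-identical across runs.

What the simulator does *not* emulate: inversions and large-scale
rearrangements (all blocks are same-orientation at the whole-chromosome
scale), codon-usage bias and rate heterogeneity across sites or genes,
sequencing noise (expression is emitted as TPM directly), and
cross-lineage gene flow. Passing recovery tests therefore demonstrates the
*statistical* correctness of each stage on cleanly structured data, not
robustness to assembly artifacts or alignment error in real genomes.

# Stage-by-stage notes

## Homology filtering

All-versus-all hit tables are filtered at e-value ≤ 1e-10 and each gene's
partner list trimmed to its best 5 (ties: higher bitscore, then
lexicographic id). A pair survives only if it survives in **both** genes'
trimmed lists; this mutual rule makes the filter idempotent, which the
property suite asserts. Self-hits are removed; pairs are deduplicated as
unordered.

## Collinear chaining

Per chromosome pair and orientation, anchors are chained by dynamic
programming maximizing summed anchor score minus a linear penalty of 1 bit
per skipped gene on either genome, with at most 25 genes between
consecutive anchors and strictly monotonic ranks. On score ties the longer
chain, then the chain with smaller starting ranks, wins — fixed so the
optimizer is deterministic and provably equal to exhaustive enumeration
(the suite checks 500 random instances of ≤ 12 anchors). Chains are
extracted best-first, consuming their anchors; chains shorter than the
4-anchor minimum (30 for macrosynteny) are discarded. Tandem arrays are
collapsed to their lowest-rank member before anchoring. For
self-comparisons the identity diagonal is excluded, and blocks whose two
rank spans overlap on one chromosome are dropped as the generalized
diagonal artifact: such "blocks" are chains of near-diagonal single-gene
duplicate anchors, not duplicated segments.

## Subgenome assignment

Blocks are packed per reference chromosome into `ploidy` non-overlapping
track slots. Packing processes whole target chromosomes (groups of blocks)
in descending total score and keeps each group in one slot — subgenomes
are chromosome-scale objects, so target-chromosome continuity outranks
local retention. A group block that collides with its own group's slot is
a duplicate chain over an already-covered region and is flagged rather
than allowed to displace another subgenome's slot. Tracks are labelled
LF ≥ MF(1) ≥ MF2 by retained gene count per reference chromosome; with the
default loss contrasts, label accuracy against truth is ≥ 99% for the 2x
lineage. When two tracks' realized retentions nearly tie on one
chromosome (possible between MF1 and MF2 at 200-gene chromosomes), their
labels can swap locally; genome-wide retention ordering is unaffected.

Genome-wide retention is reported with two denominators — all reference
genes, and only genes covered by the track's blocks — because published
percentages do not state which is used; on simulated data the two agree
to ~1 point except for heavily fractionated tracks.

The window sign test in `summarize_bias()` is computed on the
non-overlapping window subset (starts at multiples of the window size):
overlapping sliding windows are strongly correlated, and the nominal
binomial null would otherwise be anticonservative. With the default
100-gene windows this leaves 10 independent windows per 1,000-gene genome
— enough for p ≈ 0.002 under a 0.2 vs 0.5 loss contrast while staying
calibrated under equal loss (≥ 90% of null seeds give p > 0.05).

## Duplication modes

Fixed precedence wgd > tandem > proximal > transposed > dispersed.
"Ancestral locus" is operationalized as membership in any self-synteny
anchor or any genome-vs-outgroup anchor (the simulator's 1x reference
plays the outgroup). Rank distance is measured on the full gene order, not
on collapsed arrays, since the adjacency rule is stated on genes. A gene
in pairs of several modes is counted, for gene totals, under its
highest-precedence mode. Synteny outranks the hit list: a block anchor
pair missing from the homology table is kept as wgd with a warning. Under
the default planted rates the classifier recovers ≥ 97% of truth pairs
with WGD recall ≥ 98%; the proximal boundary flips exactly between rank
distances 10 and 11.

## Ka/Ks and Ks dating

NG86: per-codon synonymous site fractions from the nine single-mutation
neighbours (mutations to stops count as nonsynonymous sites), averaged
over the two sequences; differences averaged with equal weight over all
minimal mutational pathways, excluding pathways through stop codons and
falling back to all pathways when every one is blocked; Jukes–Cantor
correction applied separately to pS and pN, with saturation flagged at
p ≥ 3/4. The implementation is table-driven (64 × 64 pathway-averaged
difference matrices built once per session); the test suite re-derives
sites and differences by independent recursive enumeration. The estimator
replaces the γ-MYN estimator used by some published pipelines: γ-MYN's
rate parameters are rarely printed, and on JC-generated data NG86 is the
estimator-consistent choice; the result type leaves room for alternative
estimators.

Ks mixtures are fitted on raw Ks values in (0, 4] (a `log_space` switch
exists) by univariate Gaussian-mixture EM, 10 k-means-seeded restarts per
component count, 1–4 components, chosen by BIC. The EM asserts its
log-likelihood is non-decreasing at every iteration; variances are floored
at 1e-4 to avoid degenerate spikes. Components are labelled young-to-old
by increasing mean. A practical caveat the README example shows: the
oldest peak of a heavily fractionated lineage rests on few surviving
ohnolog pairs (~70–120 of ~450 values at the default conditions) and its
mean wobbles by up to ~0.07 around the planted 0.5.

## Syntelog counting and the retention test

For each reference query gene, every block covering its rank contributes
one syntenic region; the region contributes a syntelog only if an anchor
pairs the query itself (otherwise it is a proxy region — context without
the gene). Queries with no region in any target are excluded. Counting
uses the 4-anchor minimum and a 40-gene chaining window. Regions are
block-derived and non-overlapping per track, so a locus is never counted
twice.

The permutation test's statistic is the ratio of mean syntelog counts of
the focal set in genome X vs genome Y (closest literal reading of a "gene
copy ratio"; a difference-of-means alternative is a config switch —
the choice shapes the null but not the test's validity). The null draws
`n_perm = 1000` uniform same-sized query sets without replacement within a
draw; draws with zero mean in Y score +Inf and are flagged. Both the raw
one-sided p and the (r+1)/(n+1) correction are reported, and the test is
one-sided because the scientific claim is directional (preferential
retention in X). Null calibration is verified by a Kolmogorov–Smirnov
uniformity check over 200 independent runs.

## Expression dominance

Equal-variance Student t-tests (as the method is named, rather than
Welch — with n = 3 the choice matters), two-sided, P ≤ 0.05, no
multiple-testing correction (replicating the published procedure; reports
carry that caveat). Triads: a member dominates only if it has the top mean
and beats *both* others at alpha (a pooled-rest alternative is available).
Zero-variance groups with equal means give no call; with unequal means the
higher member is called dominant with p recorded as 0 and a
degenerate-variance flag, since the t statistic is unbounded and the
biological reading unambiguous.

# Problem sizes and reproducibility

The shipped experiments use 1,000-gene genomes for retention and
classification recovery (10 seeds), 600–900-gene genomes for the
depth-ratio trio and dominance calibration (10–20 seeds), 1,000-point
two-cluster samples for mixture recovery (20 seeds), and 200 runs × 1,000
draws for permutation calibration — sizes at which every recovery band in
the test suite is comfortably attained and a full run of tests plus
acceptance script completes in minutes on one core. All randomness flows
from explicit seeds; `run_scenario_analysis(..., out_dir =)` writes a
manifest with parameters, seed and per-file checksums, and identical seeds
reproduce identical checksums.

# Known limitations

* Subgenome tracks are labelled per reference chromosome; linking tracks
  across chromosomes into named genome-wide subgenomes (as phylogenetic
  reconciliation can) is out of scope.
* The NG86 estimator saturates above Ks ≈ 3; events older than that are
  only visible as a flagged excess, matching the Ks ≤ 4 analysis cutoff.
* The simulator's homology is exact by ancestry; the homology *filter* is
  therefore exercised by its own unit fixtures rather than by simulation.
* Real-data preprocessing (alignment of indel-containing CDS pairs, read
  mapping and TPM quantification, repeat-aware gene models) is outside the
  package: inputs are assumed clean, pre-aligned and pre-quantified.
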