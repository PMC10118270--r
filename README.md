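# syntevo

Inference of polyploid genome evolution from gene order, coding sequence
and expression — with a built-in forward simulator that makes every stage
verifiable.

Plant genomes repeatedly pass through whole-genome duplication (WGD) and
hybrid genome additions, then return toward diploidy by *fractionation*
(biased gene loss between the duplicated subgenomes). `syntevo`
re-implements, as one tested R package, the comparative-genomics inference
chain used to reconstruct such histories:

1. **Collinear blocks** — anchors from filtered homology pairs are chained
   per chromosome pair by dynamic programming (maximum summed anchor score
   minus a linear gap penalty, strict rank monotonicity, best-first
   extraction; minimum 4 anchors for microsynteny, 30 for macrosynteny).
2. **Syntenic depth** — per gene, the number of blocks of the other genome
   covering it; modal depths read out genome equivalents (a 1x : 2x : 3x
   trio shows 1:2, 1:3 and 2:3 ratios).
3. **Subgenome assignment and fractionation bias** — blocks are packed into
   `ploidy` tracks against a 1x reference, labelled LF ("least
   fractionated") to MF ("most fractionated") by retained gene count, and
   profiled in sliding 100-gene windows.
4. **Duplication modes** — homologous pairs are classified with the fixed
   precedence wgd > tandem (rank distance 1) > proximal (2–10) >
   transposed (exactly one member at an ancestral locus) > dispersed.
5. **Ka/Ks and Ks dating** — Nei–Gojobori (1986) counting with
   Jukes–Cantor correction, `d = -3/4 log(1 - 4/3 p)`, applied separately
   to synonymous and nonsynonymous proportions; WGD peaks located by
   univariate Gaussian-mixture EM on Ks ≤ 4 with BIC model choice.
6. **Retention of focal gene families** — SynFind-style per-query syntelog
   and proxy-region counts, with a permutation test (1,000 random
   same-sized query sets) for preferential retention.
7. **Expression dominance** — the "horserace": per ohnolog pair/triad and
   sample, equal-variance two-sided Student t-tests on replicate TPMs
   (P ≤ 0.05, n = 3) decide which subgenome copy dominates.

Because real polyploid genomes come without ground truth, the package
ships a forward simulator (`evolution_scenario()`, `simulate_dataset()`)
that evolves an ancestral genome through a shared WGD (target Ks 0.5), an
optional +1x genome addition (Ks 0.25), per-subgenome biased loss,
single-gene duplications of four modes, codon-level divergence under an
NG86-consistent substitution scheme, and subgenome-biased expression —
emitting GFF3/FASTA/TSV files plus a truth log, so every inference above is
tested by parameter recovery.

## Worked example

```r
library(syntevo)

scenario <- evolution_scenario(seed = 1)   # the default study conditions
res <- run_scenario_analysis(scenario)
res$recovery
#> <recovery_report>
#>   depth ratios: ref_vs_2x=1:2, ref_vs_3x=1:3, x2_vs_x3=2:3
#>   subgenome accuracy: lineage2x=1.000, lineage3x=1.000

res$fractionation$lineage2x$profile$genome_wide
#>  track n_retained n_covered retained_pct_all retained_pct_covered
#>     LF        685       996             68.5             68.77510
#>     MF        451       980             45.1             46.02041

res$ks_fit$lineage3x
#> <ks_mixture_fit> 2 component(s) over 447 values
#>     weight      mean         sd           label
#>  0.7218996 0.2498899 0.04808345 genome-addition
#>  0.2781004 0.4314886 0.14591639      shared-WGD
```

Reading: the tetraploid-derived lineage shows the expected 1:2 depth ratio
against the reference and its subgenome labels are recovered essentially
perfectly; genome-wide retention of the two tracks (68.5% vs 45.1%)
matches the simulation's realized truth to within a fraction of a point;
and the hexaploid lineage's ohnolog Ks distribution decomposes into the
younger genome-addition peak (0.250, planted at 0.25) and the older shared
WGD peak (0.43, planted at 0.5 — the older peak rests on the few ohnologs
that survive in the two most-fractionated tracks, so it wobbles more).

The `analysis/` directory holds the same chain as numbered narrative
scripts (`01_simulate.R` … `07_expression_dominance.R`); each writes its
tables under `results/` and prints what it found. Run them in order from
the repository root.

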