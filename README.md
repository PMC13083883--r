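# ythdfpipe

Post-alignment analytics for studying how the m6A reader proteins
Ythdf1/2/3 degrade methylated transcripts — including SINE/B2
retrotransposon RNAs — and thereby shape RNA polymerase II transcription in
early mouse embryos. The package is aimed at computational biologists who
have CLIP-style (LACE-seq) tag files, m6A peak calls, count tables and
CUT&Tag coverage in hand and need the downstream statistics, plus a seeded
synthetic-data generator that makes every step testable without any
external data.

## What it computes

**Binding-site calling.** Deduplicated read 5' ends are clustered per
(contig, strand) by single linkage with gap < 100 bp; clusters need more
than 10 unique reads. The summit is the position of maximal 5'-end
coverage. Each cluster is scored by

* local enrichment: density in the cluster over density in the 500-bp
  window around the summit (cluster span excluded),
* an inhibitor-control ratio
  `(n_treat / N_treat) / ((n_ctrl + 1) / N_ctrl)` against a
  methyltransferase-inhibited negative control (retained at ≥ 2), and
* a DRACH filter: the consensus `[G/A/T][A/G]AC[A/T/C]` (18 pentamers)
  must occur in the cluster span extended 30 nt upstream on the cluster
  strand.

Surviving clusters are annotated by summit (exon > intron > TE >
intergenic) and genes with exonic clusters form the reader target set.

**TE quantification.** Fractional multi-mapper counting (a read with `k`
hits contributes `1/k`, split across subfamilies), per-subfamily binding
enrichment `log2(observed/expected)` tag fractions, and Welch-t/BH
differential subfamily expression.

**Decay statistics.** Median-of-ratios size factors
(`s_j = median_i( c_ij / (prod_j c_ij)^(1/m) )`), per-gene
`log2FC = log2((kd + 0.5)/(ctrl + 0.5))` under transcription inhibition
(DRB), stratification by m6A mark (exonic peak overlap) and reader
targeting, and two-sample Kolmogorov–Smirnov comparison of the stratified
cumulative distributions, with the shift reported as the difference of
stratum medians.

**Stage patterns.** Genes are z-profiled over nine stages (MII oocyte to
blastocyst), clustered (average linkage, 1 − Pearson), and modules are
assigned to 13 template programs (maternal, minor/major ZGA, 2-cell
transient, MGA, LGA, ...) by maximal correlation; Fisher exact tests give
class-overlap enrichment of any gene set.

**Polymerase CUT&Tag.** TSS/TES metagene profiles, the pausing index
(promoter density (−50, +300) over body density (+300, TES)), differential
signal over union-merged peak regions, and Pol II fold changes binned by
distance to the nearest B2 locus (0, (0,5], (5,10], (10,20], (20,50],
(50,100], >100 kb).

**Synthetic data.** `sim_config()` + `simulate_genome()` /
`simulate_tags()` / `simulate_counts()` / `simulate_stage_counts()` /
`simulate_coverage()` generate a toy genome with planted DRACH-anchored
binding sites, m6A labels, stage programs, decay shifts, promoter pausing
and a B2-proximal Pol II effect, all byte-deterministic under one seed.
See the methods vignette (`vignettes/ythdfpipe-methods.Rmd`) for the model
and every default.

## Worked example

```r
library(ythdfpipe)
res <- run_pipeline(sim_config(seed = 1), out_dir = "ythdfpipe_out")
```

This simulates the default dataset (2 × 1 Mb genome, 300 genes, 200 TE
instances, 108 planted binding sites) and runs every stage. Selected
output:

```
> print(res$stability)
stability_report over 300 features
 contrast     group_hi       group_lo n_hi n_lo         D            p     shift
      m6a m6a_modified m6a_unmodified  122  178 0.3837723 1.098584e-09 0.3579469
   target       target     non_target   86  214 0.4959791 1.559863e-13 0.4756969
```

Reader targets are stabilised by ~0.48 log2 units relative to non-targets
under knockdown + DRB (the generator plants +0.5 on targets; the m6A
stratum shows ~0.36 because only 70% of marked genes are bound). Both KS
tests reject decisively.

```
> print(res$te_enrichment)
  subfamily observed_fraction expected_fraction      score
1   B2_Mm1a       0.028981063         0.0052005  2.4783883
2   B2_Mm1t       0.013800506         0.0026245  2.3946067
3    B2_Mm2       0.023230852         0.0026400  3.1374322
4    L1Md_A       0.009507015         0.0130550 -0.4575381
5 MERVL-int       0.021084106         0.0130685  0.6900623
```

Binding tags are enriched 2.4–3.1 log2 units on B2 subfamilies over their
genomic footprint, and not on the LINE control.

```
> print(res$b2_distance)
B2 distance stratification of 300 regions
      bin   n median_log2fc
        0   4   -0.45524569
    (0,5]   7   -0.48194316
   (5,10]   7   -0.46431336
  (10,20]  12   -0.47328261
  (20,50]  36   -0.46324064
 (50,100]  59    0.03891819
     >100 175    0.03370198
```

The planted −0.5 log2 Pol II depression is recovered in every bin within
50 kb of a B2 locus and is absent beyond — the *cis*-effect read-out.

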