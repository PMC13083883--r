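---
title: "Methods: reader binding, RNA decay and B2-linked polymerase analytics"
author: "ythdfpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reader binding, RNA decay and B2-linked polymerase analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ythdfpipe)
```

# Scope and scientific setting

In early mouse embryos the cytoplasmic m6A reader proteins Ythdf1/2/3
recognise N6-methyladenosine marks on transcripts — maternal mRNAs,
mid-preimplantation transcripts, and retrotransposon RNAs, most prominently
the Pol III-transcribed SINE/B2 elements — and commit them to decay.
Accumulating B2 RNA in reader-depleted embryos in turn dampens RNA
polymerase II activity, both globally (*trans*, via promoter-proximal
pausing) and locally around B2 loci (*cis*). This package implements the
post-alignment computational analyses this biology calls for:

1. **Binding-site calling** from CLIP-style (LACE-seq) read 5' ends, with a
   methyltransferase-inhibitor negative control and DRACH motif filtering.
2. **TE-subfamily quantification**: fractional multi-mapper counting,
   binding-read enrichment per subfamily, and differential expression.
3. **Decay statistics**: median-of-ratios normalisation, stratified log2
   fold changes under transcription inhibition, and Kolmogorov–Smirnov
   comparison of cumulative distributions.
4. **Stage-pattern classification** of genes into 13 developmental
   expression programs (maternal, zygotic genome activation waves, MGA,
   LGA, ...).
5. **Polymerase CUT&Tag analytics**: metagene profiles, promoter pausing
   indices, differential signal over merged peak regions, and
   stratification of Pol II changes by distance to the nearest B2 locus.
6. A **seeded synthetic-data generator** that emulates the structure of all
   of these inputs, so the entire pipeline is testable end to end without
   any external download.

Everything upstream of these steps — trimming, alignment, deduplication,
peak calling from coverage — is out of scope; the package consumes the
standard text formats those tools emit (FASTA, GTF, BED6, bedGraph, TSV).

# Coordinate conventions

Intervals live in `GenomicRanges` objects and therefore follow the
Bioconductor 1-based closed convention internally; BED and bedGraph input
and output are converted at the boundary (by `rtracklayer` on read, and
explicitly on write). The one deliberate exception is read 5'-end *tag
positions*, which stay 0-based exactly as they appear in the BED input;
they are single bases, so only the caller's own arithmetic touches them.
Keeping each representation native to its container avoids the usual
off-by-one traps: conversions happen in exactly two places (readers and
writers), both round-trip tested.

# The binding-site caller

The caller works per (contig, strand) on deduplicated read 5'-end
positions:

* **Clustering** — successive sorted positions are merged while their gap
  is *strictly less than* `merge_distance` (default 100 bp), i.e. single
  linkage. Clusters with `unique_reads` of 10 or fewer are discarded
  ("more than 10" read strictly).
* **Summit** — the position with the highest 5'-end multiplicity. Ties
  break towards the 5' side of the cluster strand (left-most on `+`,
  right-most on `-`), which makes output deterministic.
* **Background enrichment** — tag density in the cluster span divided by
  tag density in the 500-bp window centred on the summit, with the cluster
  span *excluded* from the background; excluding it prevents a strong
  cluster from inflating its own background. A background with zero tags
  yields an `Inf` sentinel rather than an error.
* **Inhibitor-control subtraction** — the negative control is a library
  from methyltransferase-inhibited material, where m6A-dependent binding is
  lost. The retained statistic is the library-normalised ratio of treatment
  to control tag counts in the cluster span, with a pseudocount of 1 on the
  control count; clusters below a two-fold ratio are removed. This exact
  arithmetic is a package policy (the field states the intent of control
  subtraction, not a formula); it is exposed through `caller_params()` and
  flagged as such in the documentation.
* **DRACH filtering** — the m6A consensus DRACH (D = G/A/T, R = A/G, then
  A, C, H = A/T/C; exactly 18 pentamers) must occur at least once in the
  cluster span extended 30 nt *upstream on the cluster strand*. The search
  is strand-aware (reverse complement on `-`); windows are clipped at
  contig edges; any window containing `N` at the candidate positions
  cannot match, a deliberately conservative choice.
* **Annotation** — each cluster is assigned by its summit with precedence
  exon > intron > TE > intergenic; a summit inside a TE instance always
  carries the subfamily label in addition, because a binding event on a
  repeat RNA is informative regardless of genic context. Target genes are
  genes with at least one *exonic* retained cluster (the non-intronic gene
  level), which is also the unit for reciprocal target-overlap statistics.

The enrichment statistic is tag-density based. A per-base composition
reading of "enrichment over background" exists in the field; the density
reading is the one that yields a filterable per-cluster number, so that is
what is implemented.

# TE-subfamily quantification

Multi-mapping is handled by fractional weights: a read reported with `k`
genomic hits contributes `1/k`, and a tag overlapping instances of several
subfamilies splits that weight evenly. This replaces EM redistribution
deliberately: it conserves total read weight exactly (tested), has an
exact brute-force oracle, and behaves the same qualitatively at the
subfamily level, which is the only level the pipeline reports.

Binding enrichment per subfamily is `log2(observed/expected)` on tag
fractions, with a pseudofraction of `1/(2 * total tags)` guarding empty
categories (implemented as a floor on both fractions, so the closed-form
value is exact away from zero). The expected fraction comes either from
the genomic footprint of the subfamily (default) or from a matched input
tag set.

Differential subfamily expression uses a Welch t test on log2 normalised
counts with BH adjustment — a documented simplification of
negative-binomial GLM testing, adequate for the planted subfamily-level
shifts this pipeline is designed around. Because a typical analysis has
only a handful of subfamilies, `te_differential()` accepts externally
estimated size factors; estimating median-of-ratios factors from five
subfamilies alone would absorb a genuine global B2 shift into the
normalisation. The pipeline passes factors estimated from the full
gene + TE matrix.

# Decay statistics

`size_factors()` implements median-of-ratios exactly as stated: for each
sample, the median over all-positive features of the ratio between the
sample's count and the feature's geometric mean across samples. The median
is taken in linear space (a log-space median would geometrically
interpolate the two middle values on even feature counts). Two properties
follow and are tested: factor *ratios* are exactly equivariant to scaling
any one sample, and all cross-sample contrasts of normalised counts are
invariant to such scaling. The absolute factor level is only defined up to
a constant — this is inherent to the estimator, not an implementation
choice — so all downstream statistics are contrasts.

Fold changes are `log2((mean normalised kd + 0.5) / (mean normalised
control + 0.5))`; the 0.5 pseudocount bounds fold changes of zero-count
features. Genes are stratified by two independent labels: *m6A-modified*
(at least one m6A peak overlapping the gene's exonic span; intronic peaks
do not count, matching the non-intronic treatment of targets) and
*reader target* (membership in the caller's target set). Strata are
compared with the two-sample two-sided KS test (asymptotic p, groups of at
least 5).

The reported `shift` is the **difference of stratum medians**. This
matters: when a large fraction of genes carries the planted shift,
median-of-ratios normalisation absorbs part of it into the size factors,
moving both strata; the between-stratum difference is invariant to that
and recovers the planted effect without bias (verified across seeds).

# Stage-pattern classification

Expression programs over the nine stages (MII oocyte, zygote, early/middle/
late 2-cell, 4-cell, 8-cell, morula, blastocyst) are z-scored per-gene
stage-mean profiles. Classification proceeds in three steps:

1. average-linkage hierarchical clustering on 1 − Pearson distance;
2. a static cut at height 0.25 followed by iterative merging of modules
   whose mean-profile ("eigenpattern") correlation exceeds 0.8, closest
   pair first, until stable — a deterministic, dependency-free stand-in
   for dynamic tree cutting; what matters downstream is template recovery,
   not tree topology;
3. each module goes to the template with maximal correlation to its
   eigenpattern; below 0.5 it falls back to `others`, and genes inherit
   their module's class.

The 13 templates (`stage_templates()`) are an explicit, versioned
convention of this package: the field names these classes (maternal,
minor/major ZGA, 2-cell transient, MGA peaking at 4–8 cells, LGA peaking
at morula or blastocyst, ...) but publishes no canonical parameterisation.
The shapes are unit-peak and step patterns chosen so that no pair has
positive correlation above ~0.7; with per-stage noise of SD 0.3 a gene
correlates ~0.95 with its own template, so the cut at 0.25 sits well
between within-class distances (~0.1) and between-class distances
(>0.3). `others` doubles as a concrete irregular template and as the
low-correlation fallback class. On noisy count data (as opposed to profile
draws) adjacent decaying programs (e.g. maternal and maternal-early-decay)
can merge into one module; this is expected behaviour of the static cut,
not an error.

Class-overlap enrichment of a gene set is a one-sided Fisher exact test
per class within the profiled universe (equal to the hypergeometric tail,
tested by enumeration for universes up to 50), BH-adjusted across classes.

# Polymerase analytics

Coverage is held as dense per-base vectors per contig (`coverage_track`),
normalised to counts-per-million by total signal. All profile statistics
are ratios or CPM, so they are invariant to depth scaling (tested by
doubling).

* **Metagene profiles** anchor at TSS or TES, use a ±2 kb window in 100
  bins by default, flip minus-strand genes so upstream is left, and
  exclude (but count) genes whose window leaves the contig.
* **Pausing index** is promoter density / body density with promoter
  window (−50, +300) around the TSS and body (+300, TES), transcript-
  oriented. These windows follow common pausing-index practice and are
  configurable. Genes shorter than 600 bp, with off-contig promoter
  windows, or with zero body signal are excluded with a count.
* **Differential regions**: replicate peak sets are union-merged
  (bookended intervals joined), per-region coverage sums are normalised by
  median-of-ratios, and each region gets a Welch t test on log2 counts
  with BH adjustment.
* **B2-distance stratification** bins region log2 fold changes by gap
  distance to the nearest B2-subfamily instance (overlap = bin "0"; then
  (0,5], (5,10], (10,20], (20,50], (50,100], >100 kb), reporting per-bin
  medians and KS tests between adjacent bins. This is the read-out for the
  *cis* question: is the polymerase change confined to the neighbourhood
  of B2 loci?
* **Repeat-locus metagenes** rescale each instance body to a fixed bin
  count with absolute-bp flanks, strand-oriented — the profile used for
  Pol III occupancy on B2.

# The synthetic-data generator

`sim_config()` defaults define the study conditions everything is tested
under; they are fixed once and not tuned per analysis:

| parameter | default | meaning |
|---|---|---|
| genome | 2 contigs × 1 Mb | toy scale, full pipeline in seconds |
| `n_genes` | 300 | evenly spread, both strands, 1–3 exons |
| `n_te` | 120 B2 (3 subfamilies), 40 MERVL-int, 40 L1Md_A | subfamily-labelled instances |
| `fraction_m6a` | 0.40 | genes carrying an m6A mark |
| `fraction_df_target_given_m6a` | 0.70 | marked genes bound by the reader |
| `lambda_signal` | 30 | mean tags per planted site (Poisson) |
| `lambda_background` | 0.005/bp | uniform background tag density |
| `tag_jitter_sd` | 10 bp | crosslink pile-up width around summits |
| `decay_shift_log2` | +0.5 | stabilisation of targets under kd + DRB |
| `nb_dispersion` / `te_dispersion` | 0.1 / 0.02 | count overdispersion, genes vs subfamily aggregates |
| `lib_range` | [0.5, 2] | uniform library-size factors |
| `pausing_factor` | 5 | promoter/body Pol II density ratio |
| `b2_cis_effect` | −0.5 log2 within 50 kb | Pol II depression near B2 under kd |
| `coverage_noise_sd` | 0.05 log2 | per-gene coverage noise |
| `noise_sd` | 0.3 | stage-profile noise (z units) |

Design choices worth spelling out:

* **Label counts are deterministic** (`round(n * fraction)`), identities
  random — so a configuration requesting 200 target genes plants exactly
  200 binding sites.
* **Every planted summit sits on a DRACH pentamer** written into the
  sequence on the transcript strand (reverse-complemented on `-`), and
  every reader target is m6A-marked; m6A peaks (±75 bp) are emitted over
  all planted marks. Non-target m6A genes receive the mark and peak but no
  binding site.
* **B2 instances are placed in two compact islands per contig** (anchored
  at 10% and 55% of the contig). With genes spread evenly, gene distances
  to the nearest B2 locus then populate every distance bin from overlap to
  >100 kb — a uniformly scattered B2 complement at this density would put
  nearly all genes within 10 kb of a copy and leave the far bins empty.
* **Subfamily counts use a smaller dispersion (0.02) than genes (0.1)**:
  a subfamily count is a sum over hundreds of loci, so its relative
  overdispersion is necessarily smaller than that of a single gene; with
  gene-level dispersion the planted two-fold B2 change would be
  undetectable at 3 + 3 replicates, which is not how subfamily aggregates
  behave.
* **Coverage noise is per-gene and multiplicative**, so the pausing index
  (a within-gene ratio) is exact even under noise, and `coverage_noise_sd
  = 0` gives the closed-form limit in which every eligible gene's pausing
  index equals the pausing factor exactly. The same promoter/body window
  helper is shared between the generator and `pausing_index()`; the closed
  form is a statement about consistent window definitions, and sharing the
  helper makes it hold by construction.
* The Pol II *cis* effect is applied to whole genes selected by the same
  nearest-distance rule the analysis uses (`<= 50 kb` to any B2 instance).

What the generator does **not** emulate: real sequence composition and
mappability (tags are placed, not aligned), fragment-length and crosslink
biases, instance-level TE polymorphism, EM-worthy ambiguous multi-mapping
structure, batch effects, and any coupling between expression level and
binding strength. Passing tests therefore demonstrate that the
*statistics and algorithms* behave as specified under their assumed data
model — they do not validate upstream read processing on real libraries.

# Numerical and degenerate-input policy

* Strand `.`/`*` is treated as `+` for sequence fetches; tags always carry
  explicit strand and never merge across strands.
* Empty tag sets cluster to empty tables, not errors; empty background
  windows yield `Inf`; a background window fully clipped off the contig is
  an error.
* Constant genes cannot be z-scored and are dropped from profiles with a
  message.
* KS comparisons require 5 values per group; distance bins with fewer than
  5 members report `NA` for adjacent-bin KS but still report medians.
* All randomness flows from a single integer seed per generator call;
  sibling datasets (tags, counts, coverage replicates) use fixed small
  offsets from the configuration seed so each is independently
  reproducible and the full pipeline is byte-deterministic.

# Problem sizes

The shipped tests and the acceptance script run the full pipeline on the
default 2 × 1 Mb genome (seconds per stage), the binding-recovery analysis
on 200 planted sites, decay calibration on 50 null seeds at 600 genes, and
stage recovery on 1,300 profile draws — sizes chosen so the complete suite
exercises every claim in a few minutes on one core while keeping
Monte-Carlo error well inside the asserted tolerances.

# Known limitations

* The control-subtraction ratio and the Welch-t differential tests are
  declared stand-ins for probabilistic crosslink models and NB GLMs
  respectively; both are isolated behind small interfaces
  (`caller_params()`, `te_differential()`, `differential_regions()`) if a
  heavier method is wanted.
* The static-cut clustering can merge strongly correlated adjacent
  programs at count-level noise; the class templates are a convention, not
  a community standard.
* Dense per-base coverage vectors are comfortable at toy scale but would
  need run-length or binned storage for mammalian genomes.
* `nearest_distance()` ignores strand by design; strand-aware distance
  questions need a different tool.
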