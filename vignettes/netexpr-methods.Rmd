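---
title: "Methods: differential expression, pathway net expression, and SOM clustering"
author: "netexpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential expression, pathway net expression, and SOM clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netexpr)
```

## The problem the package addresses

Immortalized cell lines are the workhorse of preclinical lymphoma research,
but long-term culture drives clonal selection, and a cell line's
transcriptome can drift far from the disease it is meant to model.  A
direct way to quantify that drift is to profile primary tumor groups,
cell-line groups, and non-neoplastic controls in the same RNA-seq
experiment and ask, per group: which genes move, in which direction, and
which pathways those movements add up to.  `netexpr` implements that
comparison as a reusable, seeded pipeline over a single gene-by-sample
count matrix:

1. two-stage expression filtering (detection, then a biotype-stratified
   low-expression percentile filter);
2. per-group negative-binomial Wald tests against the control group with
   Benjamini–Hochberg correction and three-way direction calls
   (up / down / not significant);
3. multi-group concordance analysis of the direction calls (Venn
   partitions, consistency classes against a reference group, the
   all-group core);
4. a pathway-level "net expression" score and its banding;
5. clustering of pathway net-expression profiles on a 4×4 hexagonal
   self-organizing map (SOM).

The design it targets has seven disease groups — two primary tumor groups
(B-cell lymphoma with 12 replicates, probable T-cell lymphoma with 4) and
five cell lines (CLBL-1 ×5, CLBL-1M ×5, GL-1 ×1, CL-1 ×2, OSW ×4) — plus
4 controls, 37 libraries in all; but nothing in the code is specific to
those labels or counts beyond the defaults.

## Filtering

**Detection.** A gene is *detected* if it has at least one read in at
least one library.  The detected gene set serves two purposes: it is the
input to the second filter stage, and it is the *universe* used later as
the denominator population of the pathway score.

**Percentile filter.** Within each sample and each biotype
(protein-coding, miRNA, lncRNA), the q-th percentile (default q = 0.40)
of the library-size-normalized counts of that biotype's genes is a
threshold; a gene survives if its normalized count *strictly* exceeds the
threshold in at least one sample.  Choices pinned here:

* percentile convention: linear interpolation between order statistics at
  index (n−1)·q (R's `quantile` type 7), the most widespread default;
* the percentile population is all detected genes of the same biotype in
  that sample, zeros included — stratification matters because the three
  biotype classes sit on very different expression scales, and pooling
  them would let protein-coding levels set an unreachable bar for
  non-coding genes;
* "normalized by library size" defaults to median-of-ratios size factors
  (below); a `norm = "total-count"` switch offers the simpler
  column-total reading, since either reading of that phrase is defensible.

Raising q can only shrink the retained set (monotonicity), which the test
suite checks, along with equivalence to a brute-force
sort-and-interpolate implementation.

## The differential-expression model

Counts are modelled as negative binomial with mean `mu` and variance
`mu + alpha * mu^2`; `alpha` is the per-gene dispersion.

**Size factors** follow the median-of-ratios convention: for sample *j*,
`s_j` is the median over genes (restricted to genes expressed in every
sample) of `count_gj / geometric_mean_g`, rescaled so the factors have
geometric mean 1.  If no gene is expressed everywhere the estimator
refuses and suggests total-count normalization rather than silently
degrading.

**Dispersion** is estimated by method of moments: with `m` the mean of
normalized counts and `v` the within-group pooled variance over all
groups with at least two replicates,

```
alpha_raw = max(0, (v - m) / m^2).
```

A mean–dispersion trend `a0 + a1 / m` is fit across genes by least
squares, and each estimate is shrunk toward the trend with weight `w`
(default 0.5).  Shrinkage is deliberately **one-sided**: estimates above
the trend are kept.  Pulling a genuinely high gene-wise dispersion down
toward a low trend understates the variance of exactly the genes most
likely to produce spurious extreme Wald statistics; with one-sided
shrinkage the pipeline calls nothing at FDR ≤ 1e-5 on fully null data in
19 of 20 seeded runs (see the calibration test), whereas symmetric
shrinkage left visible false positives.  Genes in singleton groups
contribute no variance information and are covered by the trend, which is
what lets a 1-replicate group (GL-1 in the default design) be tested at
all.

**The Wald test.** Each non-control group is compared to the controls
with a group-mean parameterization: the group and control log-means are
fitted separately by damped Newton iteration on the log scale (the NB
likelihood separates by group in this design, so this is exactly the
IRLS fit of the two-coefficient GLM), at the estimated `alpha`:

```
score(b) = sum_j (y_j - mu_j) / (1 + alpha * mu_j),  mu_j = s_j * exp(b)
```

`log2fc` is the coefficient difference divided by ln 2; its standard
error comes from the expected Fisher information
`I(b) = sum_j mu_j / (1 + alpha * mu_j)` of each side; `wald =
log2fc / se`; the p-value is the two-sided standard-normal tail.  The
reported `log2fc` is therefore the GLM coefficient — not a
variance-stabilized or shrunken fold change; at zero dispersion it equals
the exact log ratio of normalized group means (a property the tests pin:
counts (40, 40) vs (10, 10) give exactly 2.0).

A gene whose group (or control) counts are all zero has no finite MLE; it
is flagged non-convergent, reported with `p = NA`, excluded from that
contrast's BH vector, and logged — silently keeping such genes would
distort the BH ranks of everything else.

**Multiplicity.** BH adjustment is applied per contrast (per
group-vs-control p-vector), matching how per-group DEG counts are usually
reported.  A gene is called up if `q <= 1e-5` and `log2fc > 0`, down if
`q <= 1e-5` and `log2fc < 0`, otherwise not significant; the FDR cutoff
is a parameter everywhere.

**Known limitation.** With a single replicate against 4 controls, the
normal tail of the Wald statistic is optimistic for a single NB draw deep
in its distribution's tail: on null data, the rare false call at
FDR ≤ 1e-5 (1 run in 20) comes from that configuration.  A
likelihood-ratio or exact test would behave better at n = 1; within the
Wald framework this is documented rather than patched.

## Concordance of direction calls

Direction calls form a gene × group matrix over {+1, −1, 0}.  Three
operations consume it:

* `venn_partition` assigns every gene called in ≥1 selected group to
  exactly one combination cell, separately for up- and down-calls;
* `consistency_class` classifies genes called in a reference group as
  `concordant_up` (up in the reference, up or *unchanged* in every
  comparison group), `concordant_down` (mirror), or `discordant`.
  "Unchanged" means the absence of a call (d = 0) — no effect-size band
  is imposed;
* `all_group_core` restricts to genes called in *every* group and splits
  them by uniform versus mixed sign.  The three parts are disjoint and
  their union is the core, an identity the tests assert unconditionally.

## Pathway net expression

For pathway *p* and group *G*,

```
NE_pG = (n_up - n_down) / n_detected
```

where `n_up`/`n_down` count significantly up-/down-regulated member genes
and `n_detected` counts the pathway's members in the detected universe
(detection filter only — a gene removed by the percentile filter still
counts in the denominator).  Pathways with fewer than 20 detected members
are dropped and logged.  The denominator is the *detected* membership,
not the annotated pathway size: that is the reading consistent with
restricting the score to observable genes, and the one this package pins.
`NE` always lies in [−1, 1] and satisfies `NE * n_detected = n_up -
n_down` exactly; the emitted table carries the three counts so the score
can be recomputed from its own columns.

Values are banded as `near_zero` (|v| ≤ 0.05), `negative` (v < −0.10),
`positive` (v > 0.10), and `weak` for the remaining gap
(0.05 < |v| ≤ 0.10).  The `weak` band exists so the classification is
total; the conventional summaries only name the other three.

## The self-organizing map

Pathway net-expression profiles (one row per pathway, one column per
group) are clustered on a 4×4 hexagonal grid.  Geometry: the unit in
0-based grid row r, column c sits at `x = c + 0.5·(r mod 2)`,
`y = r·√3/2`, so all neighbouring centers are at distance exactly 1.
Unit indices are row-major and 1-based — any numbering is arbitrary, so
one is pinned for reproducibility.

Training is the classical online Kohonen rule.  The codebook is
initialized by sampling data rows (seeded).  Each epoch presents all rows
in a reshuffled order; for each row the best-matching unit (BMU, smallest
Euclidean distance, ties to the lowest index) is found and every unit
moves toward the row weighted by a Gaussian neighbourhood
`h = exp(-d²/(2 r(t)²))` over grid distance to the BMU.  Both the
learning rate (0.05 → 0.01) and the radius decay linearly over the
default 100 epochs.

The radius decays from half the grid diagonal to **0.3**.  A final radius
at or above the inter-unit distance of 1 would keep every hex neighbour
at Gaussian weight exp(−1/2) ≈ 0.61 forever: the map never leaves its
smoothing phase, and the quantization error (mean distance of rows to
their BMU codebooks) ends *above* its value at initialization on every
dataset we tried.  With a final radius of 0.3 the last epochs are
effectively winner-take-all and the trained map's quantization error
improves on its initialization whenever rows meaningfully outnumber
units.  When they do not (say, 30–40 pathways over 16 units), sampling
rows as the initial codebook is already near-optimal and *any*
topology-preserving training raises quantization error; the monotonicity
check in the test suite therefore runs at ≥200 pathways, the scale the
map is meant for (KEGG-scale collections run to a few hundred
pathways).

Inputs are not standardized: net expressions already share the [−1, 1]
scale, and rescaling would inflate the influence of near-constant
columns.

## The synthetic-data generator

`simulate_experiment()` draws a complete experiment so that every stage
is testable without external data.  It emulates:

* the default replicate structure (12, 4, 5, 5, 1, 2, 4 plus 4 controls —
  37 libraries), including the awkward singleton group;
* three biotypes with log-normal baseline means, non-coding classes lower
  (protein-coding median 150, miRNA 20, lncRNA 8 normalized counts) so
  the stratified filter has real work to do;
* NB counts with gamma-distributed per-gene dispersions (mean 0.1) and
  log-normal library-size factors (geometric mean 1, sdlog 0.2);
* planted log2 fold changes organized into pools with known downstream
  signatures: a *global core* moved in the same direction in every group
  (default 20% of planted genes), a *cell-line-only core* moved in the
  five cell-line groups, a small set of deliberately *discordant* genes
  (sign flipped in one group), and disjoint per-group *exclusive* genes;
  magnitudes are uniform on [0.5, 5] with random sign;
* gene sets assembled from those pools so that each pathway has a known
  archetype — `negative_all`, `positive_all`, `near_zero`,
  `cell_line_only` — whose net-expression sign pattern is recoverable
  *exactly* from the true direction labels, which the tests verify.

What it does **not** emulate, and what passing tests therefore do not
show: real annotation proportions (synthetic baselines are all positive,
so ~100% of genes are detected, versus ~90% of protein-coding genes in
real data); gene–gene correlation; empirical mean–dispersion trends; and
a realistic fold-change distribution — uniform [0.5, 5] magnitudes mean
most *called* genes have |log2fc| > 2, whereas in real experiments the
bulk of called genes sit within ±2.  The generator is a structural mimic
for exercising the machinery, not a distributional model of any real
dataset.

## Numerical choices and degenerate inputs

* Percentile: `quantile(type = 7)`, strict `>` against the threshold.
* Newton steps are damped to ±5 on the log scale; convergence tolerance
  1e-10 on the step, cap 100 iterations.
* `moderated_log` uses `log2(count/s_j + 1)`; the pseudocount is a
  parameter.
* PCA (`prcomp` on centered, gene-scaled data over the DEG union) drops
  zero-variance genes first and orients every component so its
  largest-magnitude loading is positive, making scores deterministic
  across linear-algebra backends.
* All randomized stages take an explicit integer seed and restore the
  caller's RNG state; two runs with the same inputs and seed produce
  byte-identical output files, which the suite asserts via checksums.
* Empty inputs fail loudly with named offenders (cell, line number, group
  label) rather than propagating NAs.

## Problem sizes used by the tests and the acceptance script

The suite runs on synthetic experiments of 400–2,000 genes with the full
37-library design; oracle-equivalence checks use 200–1,000 random small
instances per operation; calibration uses 20 seeded null runs of 2,000
genes; SOM property checks use 10 seeds.  The acceptance script runs the
default generator (2,750 genes, 40 pathways, 37 libraries) plus the
20-run null calibration; everything completes in a few seconds on one
CPU.  These sizes are the package's own choice of a desk-scale testbed
that keeps every statistical property measurable.
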