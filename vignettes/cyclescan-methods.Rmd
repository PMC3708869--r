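---
title: "Predicting cell cycle regulated promoters: models and design choices"
author: "cyclescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cell cycle regulated promoters: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Periodically expressed (cell cycle regulated) genes are classically found by
microarray time courses over synchronised cells, a design that struggles with
lowly expressed genes, synchronisation artefacts, shared probes across
transcript isoforms, and non-coding RNAs. cyclescan implements the
complementary promoter-feature route: the periodic expression program of a
gene is written in its promoter, in *trans* as binding by cell cycle
transcription factors (TFs) measurable by ChIP-seq, and in *cis* as regulatory
motif matches in the promoter sequence. A supervised classifier trained on
known cell cycle and non-cell cycle genes can therefore score any
transcription start site (TSS) — including alternative promoters and
non-coding RNA TSSs — for the probability of driving periodic expression.

## The models

### TIP regulatory scores

For one ChIP-seq signal track $s(\cdot)$ and a catalogue of $N$ TSSs, the
characteristic binding profile over strand-oriented offsets
$k \in \{-h, \dots, h\}$ is

$$c_k = \frac{1}{N}\sum_{g=1}^{N} s_g(k), \qquad w_k = \frac{c_k}{\sum_j c_j},$$

where $s_g(k)$ is the per-base signal at offset $k$ from the TSS of gene $g$,
read 5'→3' of the gene ('−' strand windows are reversed) and zero padded at
chromosome edges. The regulatory score of a gene is the weighted sum
$r_g = \sum_k w_k\, s_g(k)$ — a weighted average of the gene's own promoter
signal under the population-level weight profile. Scores are z-transformed
across genes, given one-sided upper-tail normal p-values and
Benjamini–Hochberg adjusted; target genes fall under a q threshold (default
0.01). The cited TIP scheme does not state sample vs population standard
deviation; we default to the sample sd with a `sd_type` switch
(`standardize_and_call()`).

The baseline comparator is the *average signal*: the unweighted mean of the
per-base signal in a fixed 2 kb window centred at the TSS, zero padded with a
constant denominator so scores stay comparable across genes.

Defaults: $h = 5000$ bp for TIP (a 10 kb window) and 1000 bp for the average
signal (a 2 kb window), both configurable. An optional moving-average
smoother for the profile (off by default) is available because raw per-base
averages are noisy at small $N$.

### MATCH-style motif scores

Promoters are the 1 kb upstream of each TSS on the gene's strand. A TRANSFAC
position frequency matrix with counts $n_{ib}$ is converted to frequencies
with pseudocount 1 (the source method leaves this unstated),
$f_{ib} = (n_{ib}+1)/\sum_{b'}(n_{ib'}+1)$, and position information weights
$I_i = \sum_b f_{ib}\ln(4 f_{ib})$. A window with bases $b_1 \dots b_L$
scores $\sum_i I_i f_{i b_i}$, min–max normalised over the attainable range
to the matrix similarity score (mss) in $[0,1]$; the core similarity score
(css) applies the same formula to the matrix core (the annotated core, or the
5 consecutive most informative positions). Both strands are scanned; `N`
bases score the per-position minimum. Retained hits need
`mss ≥ cutoff_mss` and `css ≥ cutoff_css`.

MATCH's proprietary minFP cutoff profiles are not redistributable, so cutoffs
come from a sidecar table when available and otherwise default to
mss ≥ 0.85, css ≥ 0.75 — a reproducible substitute in the range the published
profiles occupy. The gene × motif score `B[i, j]` aggregates retained hit
scores; "aggregation" is read as summation (the score grows with site count),
with max-aggregation behind a flag; no hit gives exactly 0.

### The classifier

`cycle_forest()` is a classification random forest: CART trees grown to
purity on bootstrap samples, Gini splitting over $\sqrt{P}$ random candidate
features per split, 500 trees by default, probabilities as the fraction of
trees voting positive. No forest package exists in the target environment,
so the forest is implemented in compiled code inside the package with the
classic semantics. Feature importance is reported both as mean decrease in
Gini (MDG, from the training forest) and as an out-of-bag permutation
importance on the squared-error scale (the %IncMSE analogue; 10 permutations
per feature, averaged). The original analysis quotes both measures in
different places; both are first-class here and the discrepancy is surfaced
rather than resolved.

Evaluation is 10-fold cross-validation with *unstratified* folds — the
original protocol partitions "irrespective of binary assignment" — with a
stratified option behind a flag. The ROC sweeps 100 equally spaced threshold
partitions of the score range plus endpoints and integrates by the trapezoid
rule; the exact rank-statistic (Mann–Whitney) AUC is computed alongside and
the two agree within 0.01 on any input with enough distinct scores, which the
tests assert.

Feature ablation re-estimates importance after every removal (ties broken
lexicographically for determinism); the top-k model re-runs cross-validation
on the `k_tf` + `k_motif` most important features of the full model.
Phase-specific models select positives by Cyclebase-style peak-time ranges —
M/G1 [95,100)∪[0,20), G2/M [80,95), G2 [70,90), S [47,70), G1/S [20,60) —
which overlap by construction, so one gene may train several phase models.
Expression-matched negative sets are drawn by quantile-bin matching
(two-sample KS p > 0.1 as the adequacy check) to decouple the expression
confounder discussed below.

### Genome-wide prediction and empirical FDR

A trained model scores any TSS catalogue. As a null, `random_tss()` draws
artificial TSSs uniformly over the genome (counts proportional to chromosome
length, uniform strand). At a probability threshold $t$, with $F_{real}$ and
$F_{rand}$ the fractions of real and artificial TSSs scoring above $t$, the
empirical false discovery rate is $F_{rand}/F_{real}$ and the precision is
$1 - FDR$ where defined. "Evenly distributed" is read as plain uniform
sampling without exclusion zones (the original controls were plain random
locations); an optional exclusion set is provided because random draws can
hit true promoters. This estimator is unbiased only insofar as artificial
TSSs behave like negative promoters; the calibration test below constructs
exactly that regime, and the limitation is inherited from the original
design, not removed by it.

### Validation statistics

Circular sliding-window enrichment maps peak times (0–100) onto degrees by
$\theta = 3.6 \cdot$ peak time (the original analysis speaks in degrees but
stores peak times on a 0–100 scale and never states the mapping; ×3.6 is the
only linear surjection). Windows are 30° wide every 20° — "10 degrees
overlapping" between neighbours — giving 18 windows, each tested by a
one-sided Fisher exact test. Gene-set overlaps use one-sided Fisher tests
with an *explicit* universe, because the original universe is not stated and
the p-value is sensitive to it. Protein-interaction partner statistics
report per-class mean partners, mean cell cycle partners and mean percentage
of cell cycle partners, with pairwise chi-squared tests on aggregate partner
counts.

## The synthetic world

`simulate_cycle_data()` generates every input from a seed: genome, TSS
catalogue with planted labels (peak times uniform on [0,100)), per-TF signal
tracks, motif matrices and planted instances, expression, a PPI network,
knockdown screens and a truth record. The stated world:

* geometry — 2 chromosomes × 2 Mb, 1000 genes (the full pipeline stays
  under a few minutes on one CPU); ~3% of genes are cell cycle regulated,
  the genome-wide prevalence the method reports. Classifier-level tests use
  balanced training sets of a few hundred genes per class, mirroring the
  original training design (∼850 positives vs ∼1050 negatives), with gene
  spacing ≥ 8 kb so wide profile windows do not absorb neighbouring genes'
  peaks.
* binding — a gene is bound by a TF with probability
  `plogis(qlogis(0.15) + label·log(tf_effect) + 0.8·expression)`, with
  `tf_effect = 4` for the 8 informative of 20 TFs and an optional
  phase-preference boost for phase-specific tests. Bound genes get a
  Gaussian peak (height 10, sd 150 bp) over a lognormal(0, 0.5) background
  drawn per 25 bp and linearly interpolated — smooth, positive,
  realistic-looking coverage.
* peak offsets — N(0, **800 bp**) from the TSS. This is a deliberate,
  load-bearing choice: when peaks sit tightly at the TSS (say sd 300 bp), a
  fixed 2 kb window already captures all binding mass and weighted profile
  scoring cannot outperform the plain window mean — the two statistics
  converge to the same binding-probability limit and their contrast
  comparison becomes a coin flip. Binding sites spread over a couple of
  kilobases are exactly the regime that motivates a wide, learned weight
  profile, and only in that regime is the documented TIP-vs-average
  advantage reproducible.
* motifs — 10 bp matrices with one strongly dominant base per position
  (counts 200 vs 1), so instances sampled from the matrix frequencies carry
  ≤ 1 mismatch ~99% of the time and clear the default cutoffs (one mismatch
  keeps mss ≈ 0.9, css ≈ 0.8). Informative motifs are planted in 40% of
  positive and 10% of negative promoters; uninformative motifs at 10%
  everywhere.
* confounder — cell cycle genes are expressed 1.5 sd higher, and expression
  couples into binding odds for *every* TF. This reproduces the documented
  confounding: uninformative TFs separate the classes through expression
  alone, and only expression-matched negatives isolate the genuinely planted
  effects.
* networks and screens — PPI edges oversample cell cycle endpoints (odds 3);
  knockdown screens hit true cell cycle genes at rate 0.3 and background
  genes at 0.05.

What a green test does *not* establish: the generator plants single
Gaussian-peak binding events on an i.i.d. background — real ChIP-seq has
multi-site promoters, mappability structure, GC bias and copy-number
artefacts; promoters are uniform random sequence, so motif background rates
are lower than in CpG-rich real promoters; expression enters as a single
Gaussian covariate. Passing tests demonstrate that the statistics and the
pipeline recover planted structure under the stated assumptions, not that
the biological effect sizes of the original study are reproduced.

## Numerical and edge-case choices

* Coordinates are 0-based half-open throughout; BED is native, wiggle is
  shifted on read. A '−'-strand BED feature's TSS is `end − 1`.
* Uncovered bases read as signal 0; windows truncated at chromosome edges
  are zero padded with unchanged denominators.
* An all-zero characteristic profile (weights undefined) and an all-equal
  score vector (sd 0) are explicit errors, not NaNs.
* Tree split points are midpoints between adjacent distinct values; ties in
  importance rankings break lexicographically by feature id; every source of
  randomness (bootstrap, feature subsets, folds, permutations, simulation)
  derives from caller-supplied seeds.
* FDR is reported unclipped, with a display column clipped at 1; PPV is
  defined only where FDR ≤ 1. `F_real = 0` raises an explicit
  no-positive-predictions error.
* The random-TSS count is a free parameter (the source quotes both "10,013"
  and "∼10,000"); no motif- or gene-count totals are imposed anywhere, since
  the source text is internally inconsistent about them.

## Known limitations

* The forest is a faithful but compact reimplementation; exact vote-level
  agreement with any particular external forest implementation is neither
  expected nor required — properties are asserted against planted truth and
  rank statistics instead.
* Pre-selection of TF features ("81 TFs" in the original training) has
  unstated criteria; the package exposes feature subsets as explicit id
  lists and never infers them.
* The empirical FDR inherits the assumption that random genomic locations
  are a faithful negative model; where negatives carry real but
  class-uninformative binding, it underestimates the truth. This is a
  property of the estimator, reproduced as documented.
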