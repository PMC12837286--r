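---
title: "Benchmarking cell-type deconvolution with simulated pseudo-bulks"
author: "SimDeconv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking cell-type deconvolution with simulated pseudo-bulks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SimDeconv)
```

# The problem

Bulk RNA-seq measures the average expression of a mixed cell population.
Deconvolution methods model a bulk profile $b$ as a non-negative
combination of cell-type expression profiles, $b \approx S f$, where $S$
is a gene-by-cell-type signature matrix and $f$ the vector of cell-type
fractions. Second-generation methods learn $S$ from an annotated
scRNA-seq reference. Benchmarking such methods requires bulk samples with
known composition; pseudo-bulks — sums of sampled single-cell profiles —
provide exactly that, and, because the sampling is fully controlled, they
let us isolate individual failure modes: mRNA-content bias, spillover
between similar cell types, unknown cell types absent from the
reference, and the resolution of the cell-type annotation.

SimDeconv packages this workflow end to end: a synthetic reference
generator, quality control and subsampling, a scenario-driven pseudo-bulk
simulator, signature construction and scoring, two in-house reference
solvers (NNLS and a dampened weighted least squares), and the benchmark
experiments with their metrics.

# The synthetic reference generator

`generateReference()` draws counts from a gamma–Poisson (negative
binomial) model with type-specific gene means — the standard two-parameter
description of scRNA-seq overdispersion. Each cell type expresses

* an exclusive block of marker genes, elevated `markerFold`-fold
  (default 5) over the background, and
* a random subset of a background gene pool shared across types.

The size of that subset is solved numerically so that the *expected
number of nonzero genes per cell* equals the type's
`expressedGeneTarget`. The nonzero-gene count is the package's proxy for
mRNA content: types that express more genes contribute more mRNA per
cell. Controlling it through the expressed-set size (rather than an
explicit capture-efficiency model) keeps the generator simple while
making the realized per-type means land within a few percent of the
target; a 10% agreement is asserted in the tests.

Remaining knobs, with defaults chosen as typical desk-scale conventions:
`meanLibrarySize` (counts per cell; 20,000 by default, 5,000–8,000 in the
fixtures), NB `dispersion` (size parameter, 2), per-cell library-size
spread (`librarySdLog = 0.15` on the log scale), donor labels assigned
round-robin, and mitochondrial fractions drawn Beta(2, 40), a typical
healthy range that gives the QC filter realistic input. Dispersion and
abundance spread are conventions, not estimates from any particular
dataset: published references do not come with fitted dispersions.

The optional `shareProfileWith` field lets one type copy another's
background profile exactly, so that the two differ only in their small
marker blocks. This yields *controlled transcriptional similarity* — the
ingredient needed to study spillover and leave-one-cell-type-out mass
redistribution — and, with `nMarkers = 0`, an exact null for the marker
selection test.

What the generator deliberately does **not** emulate: doublets, ambient
RNA, batch effects beyond the donor label, UMI-versus-read distinctions,
gene length (hence no TPM), or the heavy-tailed abundance structure of
real transcriptomes beyond a log-normal. Tests passing on these fixtures
show the pipeline's internal consistency under the stated model; they do
not certify performance on real tissue.

# Quality control and subsampling

`madOutlierFilter()` removes cells whose total counts or expressed-gene
counts deviate from the median by more than 5 raw MADs (two-sided), or
whose mitochondrial fraction exceeds the median by more than 3 MADs
(upper-sided — low mitochondrial content is not a defect). The MAD here is
`median(|x - median(x)|)` without the normal-consistency constant
(`madStat()`), matching the robust-QC convention the rule is drawn from.
The literature sometimes prints this rule in a shorthand that reads as a
comparison of the value itself against `n*MAD`; taken literally that is
not a deviation test, so the standard deviation-from-median form is
implemented.

`subsampleReference()` covers the three rules used when assembling
training references: a fixed fraction per type (rounded up with
`ceiling()` so small types are never emptied; types under 20 cells are
kept whole), a fixed total with per-type counts assigned by
largest-remainder apportionment (the natural reading of "keeping
proportions matched"), and a per-type cap (e.g. 500 cells per type before
signature training). All sampling is without replacement and
seed-deterministic.

# The pseudo-bulk simulator

`simulateDataset()` realizes five composition scenarios
(`mirror_fractions`, `mirror_db`, `random`, `pure`, `weighted_spike`).
For each sample, integer per-type cell counts come from largest-remainder
rounding of the target fractions (`drawCellCounts()`, deterministic, ties
broken by fractional part then label order); cells are then drawn
uniformly *with replacement* within each type, their count vectors summed,
and the aggregate rescaled so every sample has exactly the configured
sequencing depth (default $10^7$; rescaling is deterministic rather than
multinomial because downstream metrics are scale-free). Random
compositions use a flat Dirichlet; in `weighted_spike` the spike type is
fixed at its level and the remainder split by a flat Dirichlet — the
generic reading of "random fractions" for the remaining types.

Two design points carry the mRNA-bias machinery:

* **Scaling factors.** With `biasMode = "expressed_genes"`, each drawn
  cell's counts are multiplied by its nonzero-gene count divided by the
  reference-wide mean (`computeScalingFactors()`), so factors average 1
  and bias changes relative, not absolute, contributions.
* **Cell-count ground truth.** The recorded truth is the fraction of
  *cells* per type, never the mRNA-weighted share. Under bias the
  expression and the truth therefore disagree by construction — that
  asymmetry is what the ΔRMSE analysis measures.

Per-sample seeds are derived as `seed + sample index`, so two runs
differing only in `biasMode` draw *identical* cells: ground truths are
equal element-wise, and with unit factors the expression matrices are
bit-identical (the `factors` argument of `simulateDataset()` accepts an
explicit override for such sensitivity checks). Expression is emitted on
a counts scale; CPM is available via `cpmNormalize()`. TPM is undefined
without gene lengths and out of scope.

# Signatures and their quality scores

`selectMarkerGenes()` runs a one-vs-rest Wilcoxon rank-sum test per cell
type on CPM values (normal approximation with tie and continuity
correction), keeps genes with Benjamini–Hochberg adjusted $p <$
`pvalCutoff` (default 0.05) and positive log2 fold-change, ranks by
fold-change and caps at 200 genes per type. The rank-sum test replaces
heavier hurdle-model machinery on purpose: it is desk-scale, assumption-
light, and adequate for marker gating; applying BH *before* the cutoff is
the stricter of the two readings of an unqualified "p-value cutoff".
`buildSignature()` then records the mean CPM per type over the selected
genes.

Three scores summarize signature quality:

* **Entropy specificity** per gene: $1 - H(p)/\log_2 C$ with $H$ the
  Shannon entropy (bits) of the gene's normalized row and $C$ the number
  of types — 1 for a one-hot (perfectly specific) gene, 0 for uniform
  expression. The normalization by $\log_2 C$ is inferred from the
  stated 0/1 endpoints of the score.
* **Gini index** per gene: $\sum_{ij}|x_i-x_j| / (2 n^2 \bar x)$, 0 for
  equal values; an all-zero vector is defined as 0 with a warning.
* **Condition number** $\kappa = \sigma_{\max}/\sigma_{\min}$, the
  singular-value-ratio generalization of $\|M\|\|M^{-1}\|$ to the
  rectangular gene-by-type case (what numerical `kappa` routines return
  for non-square input). Rank-deficient signatures report `Inf` together
  with a diagnostic naming collinear column pairs.

# Solvers

`nnlsDeconvolve()` solves $\min\|Sf-b\|_2,\ f \ge 0$ per sample
(Lawson–Hanson active set) on the intersected gene set, with the bulk
column CPM-normalized first and the estimate rescaled to sum to 1. Gene
matching is exact and case-sensitive; an overlap below twice the number
of types is an error rather than a silent degraded fit.

`dwlsDeconvolve()` iterates weighted NNLS with per-gene weights
$w_g = 1/\max((Sf)_g, \varepsilon)^2$, $\varepsilon = 10^{-8}$ guarding
undetected types. Unrestrained, these weights let a handful of
near-zero-expression genes dominate, so they are *dampened*: scaled to
minimum 1 and capped at $2^j$, with the exponent $j \in \{1,\dots,30\}$
chosen once per sample by 5-fold cross-validation over genes, minimizing
the held-out weighted residual. Folds are assigned round-robin over the
gene order, making the whole solver deterministic without any RNG state;
the exponent is selected from the initial NNLS-based weights and held
fixed across iterations (re-selecting each iteration would multiply the
cost ~150-fold for no observed benefit on fixtures). Iteration stops when
the fractions change by less than `tol` in the infinity norm;
non-convergence is flagged in the provenance, never thrown, so benchmark
sweeps cannot abort mid-way. The dampened weighting is what gives the
solver its advantage on rare cell types, whose signal lives in
low-expression genes that plain NNLS effectively ignores.

# Experiments and metrics

`evaluateFractions()` computes the metric set: global Pearson correlation
(pooled over all sample-type pairs, on raw values — the literal reading of
"across all fractions and samples"), per-type Pearson, per-sample and
per-type RMSE, MAE, and MAPE. MAPE excludes zero-truth entries and
reports their count rather than inventing a pseudo-count. Correlations of
constant vectors (e.g. a type estimated as all zeros) carry an explicit
`undefined` flag instead of propagating NaN.

* `deltaRmseBias()` — per-type RMSE difference between paired bias and
  no-bias arms; positive means the pipeline does not correct mRNA bias
  for that type. Pairing (identical sample seeds) is verified from the
  report provenance. Note that rescaling the signature columns by
  per-type mean scaling factors corrects the *biased* arm only; applying
  the corrected signature to the unbiased arm simply moves the error
  there, so the shrinkage check applies the correction where bias exists.
* `spilloverExperiment()` — pure pseudo-bulks per type; the mean
  estimated percentage on the true type (ideally 100) and on every other
  type; rows are compositional by the sum-to-one constraint.
* `unknownContentExperiment()` — `weighted_spike` simulations at
  increasing spike (e.g. tumor) levels, deconvolved with a signature
  trained on the known types only (capped at 500 cells/type). The primary
  comparison uses the unnormalized truth (known-type mass $1-$level),
  because the inflation of sum-to-one estimates *is* the estimation bias
  under study; the renormalized comparison is reported as secondary.
* `granularityExperiment()` — one fine-level simulation deconvolved with
  signatures at each annotation level, plus the aggregation strategy
  (fine estimates summed to coarse via `aggregateFractions()`, which
  preserves row sums exactly and therefore commutes with normalization).
* `leaveOneOutExperiment()` — signatures rebuilt without each type in
  turn; the per-type RMSE difference against the full reference shows
  which types absorb the removed type's mass.

All experiments accept any solver satisfying the fraction-matrix
contract (`"nnls"`, `"dwls"`, or a function), so externally produced
estimates can be evaluated through the same machinery via the
fraction-CSV import path.

# Numerical choices and degenerate inputs

Largest-remainder rounding everywhere integer counts are needed, with
deterministic tie-breaking. CPM treats a zero-sum column as an error
naming the column. An all-zero estimate row cannot be normalized and is
an error naming the sample. Condition numbers use the machine-epsilon
scaled rank test of the SVD. The weight floor $\varepsilon = 10^{-8}$ and
the dampening grid $2^1 \dots 2^{30}$ follow common practice for this
solver family. Label matching is exact and case-sensitive, with no gene
symbol aliasing.

# Problem sizes

The shipped tests and the acceptance script run entirely on generated
fixtures, sized so the full pipeline stays at desk scale while keeping
sampling noise well below the tested margins: references of 2–5 types
with 120–500 cells per type and 2,000–3,000 genes; pseudo-bulk runs of
25–50 samples at 5,000–10,000 cells and depth $10^6$–$10^7$; the
unknown-content protocol at its full 9 levels × 5 replicates × 10 samples
(450 pseudo-bulks) on a 2,500-cell reference; and the bias compendium at
8 references × 50 samples × 2 paired arms (800 pseudo-bulks).

# Known limitations

The generator's background abundances are log-normal and shared across
types, so between-type distances are more homogeneous than in real
atlases; spillover magnitudes on fixtures are therefore optimistic.
mRNA-content differences enter only through the expressed-gene count,
not through library-size differences at equal gene counts. The DWLS-style
solver fixes its dampening exponent from the initial solution; pathological
mixtures could in principle prefer a different exponent after reweighting.
Real-data ingestion is limited to plain-text formats (Matrix Market + TSV,
CSV); no HDF5/AnnData container support.
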