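---
title: "Conditional modelling of gene expression from promoter chromatin state"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional modelling of gene expression from promoter chromatin state}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitree)
```

## The problem

Genome-wide regression of transcript abundance on promoter-localised
chromatin signal is a standard exploratory tool: the fitted coefficients
and the model's predictive accuracy are read as evidence about regulatory
roles, not as a gene-by-gene predictor. A persistent obstacle is that the
association between a histone mark and expression is *conditional* on other
epigenetic state. Two canonical examples drive this package:

* **Methylated promoters.** Dense promoter CpG methylation silences a gene
  regardless of what the histone marks would otherwise predict. A
  methylation score is strongly anti-correlated with expression, yet
  appending it as one more column of a linear model adds almost nothing,
  because across the genome it is statistically redundant with marks such
  as H3K9me3.
* **Bivalent promoters.** Where the H2A.Z histone variant accompanies both
  H3K4me3 and H3K27me3, the two marks are held in a poised equilibrium and
  H3K4me3 — elsewhere the strongest activating signal — becomes a hallmark
  of low expression. A single genome-wide coefficient per mark cannot
  represent a sign that flips with context.

The package's answer is a binary decision tree whose *leaves* are ordinary
linear expression models over disjoint gene classes and whose *internal
nodes* are unsupervised categorisation steps on one score column (e.g.
promoter methylation, then H2A.Z). The classes are latent: only the tree
topology is supplied (or enumerated exhaustively); the thresholds are
learned from the data.

## From reads to scores

All coordinates are 0-based, half-open (BED convention); GTF input is
converted on read. Each gene keeps a single, most 5' TSS per gene
identifier (minimum start on `+`, maximum end−1 on `-`).

**Histone scores.** For gene $i$ and mark $j$ the score $a_{ij}$ counts the
ChIP-seq reads whose shifted 5' end falls in the window
$[\mathrm{tss}-w,\ \mathrm{tss}+w)$ with $w = 2000$ bp. Reads are reduced
to their 5'-most base and shifted by $\pm 73$ bp ($+$ for `+`-strand
reads, $-$ for `-`-strand reads): ChIP fragments are sequenced from
nucleosome ends, so half a nucleosome's length re-centres each read on the
modified nucleosome. The half-width of 2000 bp approximates the width of
promoter histone-modification domains; both values are `scoring_config()`
defaults and can be changed coherently across histone and methylation
scoring. Reads are *not* deduplicated or depth-normalised here — any
per-read table, normalised upstream or not, is accepted.

**Methylation scores.** Four gene-level summaries of per-CpG RRBS counts
over the same window are provided:

| score | definition | reading |
|-------|------------|---------|
| SMFS  | $\sum_c m_c/n_c$ | methylation mass (confounded with CpG density) |
| MMFS  | SMFS / #assayed CpGs | mean methylation level |
| MMFR  | $\sum_c m_c / \sum_c n_c$ | read-weighted level |
| SMRR  | $\sum_c m_c\, e^{-|d_c|/d_0}$ | TSS-proximity-weighted methylated reads |

with $m_c$ methylated reads, $n_c$ coverage and $d_c$ the CpG's distance
from the TSS ($d_0 = 5000$ bp). Only CpGs with coverage > 0 are "assayed"
and enter MMFS's denominator; a gene whose window contains no assayed CpG
gets `NA` and is carried as masked rather than silently zeroed (the
augmentation step can impute 0 — unassayed RRBS regions are typically
CpG-poor and unmethylated — or drop the genes). The SMRR weight is
implemented as the *decaying* exponential $e^{-|d|/d_0}$; a
`smrr_literal` flag preserves the unbounded form $-e^{|d|/d_0}$ for
comparison, but that form contradicts the decaying affinity score the
method descends from and is not recommended.

## The regression model

Expression is modelled on the arsinh scale,

$$\operatorname{arsinh}(y_i) \;=\; \mu + \sum_j \beta_j\, x_{ij} + \varepsilon_i,$$

where $\operatorname{arsinh}(x) = \log(x + \sqrt{1+x^2})$ behaves like
$\log(2x)$ for large $x$ but is defined at $x = 0$, so zero-RPKM genes need
no pseudo-count (whose choice would otherwise be a hidden tuning knob). By
default the predictors are also arsinh-transformed,
$x_{ij} = \operatorname{arsinh}(a_{ij})$: tag counts have heavy right
tails that would otherwise dominate the least-squares fit. Setting
`transform_predictors = FALSE` in `fit_linear()` restores the raw-score
design for comparison.

Accuracy is always reported as adjusted $R^2$,
$1 - (1-R^2)\frac{n-1}{n-p-1}$, which removes the expected in-sample gain
of adding explanatory variables; `evaluate_model()` additionally offers
10-fold cross-validation (pooled out-of-fold predictions scored once) and
replicate holdout (fit on one RNA-seq replicate, score against the other).
Inside the threshold search the in-sample adjusted statistic is used — the
adjustment is what makes thousands of candidate fits affordable and
comparable — while final class accuracies can be re-scored by CV.

**Regulatory roles.** `pca_decompose()` takes the SVD
$\operatorname{arsinh}(A) = U\Sigma V^{\mathsf T}$ of the (column-centred)
transformed score matrix; `derive_roles()` regresses expression on each
principal component alone and returns the loadings of the most predictive
component, with signs oriented so that the selected component correlates
positively with expression — positive loadings then read as
activator-like, negative as repressor-like. Centring is the statistical
default; `center = FALSE` reproduces the raw SVD. Columns are not variance
scaled, so loadings retain the marks' natural (arsinh) scales. PCA signs
are otherwise arbitrary; the orientation convention is ours. Ties in
per-component predictiveness resolve to the lowest index with a warning.

## The decision tree

A structure such as `"(MMFS:(H2A.Z:H2A.Z-|H2A.Z+)|MMFS+)"` declares:
split all genes on MMFS (score $\le \gamma$ goes left); the right child is
the `MMFS+` class; the left child splits again on H2A.Z into `H2A.Z-` and
`H2A.Z+`. Leaf models drop the split variables along their path — the
class membership already encodes that information, and retaining the
variable would re-introduce the redundancy the split resolved — and keep
everything else (`MMFS+` keeps H2A.Z as a predictor, for instance). The
leaves partition the gene set; internal-node models are used only to set
thresholds.

**Threshold selection.** `scan_threshold()` walks a grid of candidate
$\gamma$ (unique empirical quantiles of the split column at 1% steps,
implemented as the $\lceil pn\rceil$-th order statistics so every 1% cut
is exactly representable; candidates leaving either side below
$\max(50, p+2)$ genes are excluded). At each $\gamma$ it fits leaf-style
models to both sides and records three $\Delta$adj-$R^2$ curves against a
genome-wide baseline model — by default the *augmented* standard model on
all supplied columns, histone marks plus methylation, with its adjusted
$R^2$ recomputed on the evaluation subset (a histone-only baseline is one
option away via `baseline_columns`):

* `delta_negative` — left model vs baseline on the left genes;
* `delta_positive` — right model vs baseline on the right genes;
* `delta_cumulative` — one adjusted $R^2$ over the concatenated
  predictions of both sides (with $p$ = number of distinct predictor
  columns used) vs the baseline on all genes.

`fit_tree()` chooses each node's $\gamma$ greedily, top-down, by
maximising the **cumulative** curve. This is a deliberate design choice:
the single-side objectives are degenerate on exactly the data the method
targets. When one side is a homogeneous, low-variance class (deeply
methylated, near-silent genes), its own $\Delta$ curve plateaus across
every threshold that keeps the side pure and drifts upward as the side
shrinks — the baseline's adjusted $R^2$, recomputed on a small
near-constant subset, diverges to large negative values — so its argmax
wanders into extreme quantiles. The cumulative objective is instead pulled
down whenever *either* side is contaminated, and peaks at the class
boundary. The single-leaf-child variant (optimise the lone leaf's own
curve) remains available as `tree_options(scenario = "leaf")` for
comparison. Ties at $\gamma$ route left (`score <= gamma`); genes with a
missing split score route to the low side by default (unassayed
methylation reads as unmethylated; `missing = "right"` flips this), with
counts visible in the scan object.

**Null calibration.** With `n_null > 0` each grid point is accompanied by
the chance-level $\Delta$: a class-style model refit on a randomly sampled
gene set of the matching class size, compared with the standard-style
model refit on the same random genes, centred on that model pair's
whole-gene-set delta. The centring removes the dataset's fixed redundancy
offset — the realised in-sample cost of dropping the split column, which
every subset inherits and which would otherwise sit several standard
errors from zero at large class sizes — so the null mean is ~0 at every
size and the standard error quantifies pure gene-set sampling variation,
growing as the class shrinks. An observed $\Delta$ well outside the null
band is evidence of genuine conditional structure at that threshold.

**Exhaustive search.** `enumerate_structures()` lists every binary tree up
to a depth cap with no variable repeated on a root-to-leaf path;
`exhaustive_search()` fits them all greedily and ranks by cumulative
adjusted $R^2$. Two caveats are inherent and worth knowing. Greedy
per-node thresholds are not a joint optimum over all thresholds (a joint
search would also abandon the per-node "regulated or not" reading).
And split *order* is often unidentifiable: when two categorisation
variables induce the same gene partition in either order, the two
orderings differ only by fit noise, so the winner's root variable should
not be over-interpreted — the set of variables used is the robust
statement. The depth-1 rankings are where single-variable dominance is
legible.

## The synthetic study conditions

`simulate_dataset()` generates matched tag files, an RRBS table and a
two-replicate expression table over a toy chromosome of well-separated
genes (50 kb spacing, so promoter windows never overlap), with four
planted classes echoing the promoter code above:

| class | marks | methylation | expression |
|-------|-------|-------------|------------|
| silenced (40%) | high H3K9me3 | Beta(9,1) | near zero, weak depth gradient |
| bivalent (20%) | H3K4me3 + H3K27me3 + high H2A.Z | Beta(1,9) | low; H3K4me3 mildly repressive |
| active (25%) | high H3K4me3 | Beta(1,9) | high; +H3K4me3 −H3K27me3 |
| repressed (15%) | high H3K27me3 | Beta(1,9) | low; same coefficients as active |

Tag counts are Poisson with per-gene Gamma(shape 3) rate heterogeneity —
real ChIP-seq coverage is overdispersed, and without that heterogeneity
within-class score variation would be unrealistically tight. Tag centres
are Normal(0, 300 bp) around the TSS, written as strand-shifted 5' read
ends so that re-scoring the emitted files reproduces the generator's
internal realised scores *exactly* (an end-to-end identity the tests
assert). Per-CpG coverage is Poisson(10) over 20 CpGs per promoter;
methylated reads are Binomial around a per-gene Beta level. Expression is
class-conditional and linear on the arsinh scale in the realised scores
(intercepts 1.2/1.5/0.5/0.5; silenced genes carry a weak
repression-depth gradient, −0.35 on arsinh H3K9me3, reflecting residual
transcription at silenced promoters), clipped at zero and noised with
$\sigma_\varepsilon = 0.5$ on that scale, independently per replicate.
These defaults were fixed once as a plausible caricature of the target
biology, not tuned to any test outcome.

What the generator deliberately does **not** emulate: mappability and GC
bias, input/IgG background, CpG-island structure, overlapping or nested
genes, inter-gene correlation, and count-level expression noise. Passing
tests on these conditions therefore demonstrate the machinery —
score arithmetic, estimator calibration, threshold recovery, class
assignment — not performance on real chromatin, where class boundaries
are softer and redundancy patterns richer.

## Numerical notes and degenerate inputs

* OLS is solved by QR; a rank-deficient design is an error naming the
  collinear columns rather than a silent drop. A constant response yields
  $\beta = 0$, $R^2 = 0$ by convention.
* `adjusted_r2()` requires $n > p + 1$ and non-degenerate observed
  variance; inside the scan those conditions simply mark a grid point
  `NA`, which the argmax skips.
* Empty tag or RRBS overlap is a score of 0 / a masked gene, never an
  error; chromosomes absent from a file behave the same way.
* Reproducibility is exact: every stochastic step (generator, fold
  assignment, null sampling) is governed by an explicit integer seed, and
  the text writers emit full double precision (`%.17g`), so identical
  seeds give hash-identical files.

## Limitations

Thresholds are axis-aligned cuts on single scores; interactions that need
oblique boundaries are out of scope, as are regularised or count-likelihood
models. The cumulative objective evaluates in-sample (adjusted); a
CV-scored search would be slower and noisier but is available to the user
via `evaluate_model()` on fixed classes. Class labels are assignments, not
probabilities — genes near a threshold are assigned as confidently as genes
far from it.
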