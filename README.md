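# epitree

Conditional gene-expression modelling from promoter chromatin state.

`epitree` is for computational biologists who use genome-wide regression of
transcript abundance on promoter chromatin signal as an exploratory tool —
reading coefficients, PCA loadings and prediction accuracy as evidence
about regulatory roles. Standard single-model regressions cannot represent
*conditional* regulation: promoter DNA methylation silences genes
regardless of their histone marks (yet adds nothing when naively appended
to a linear model, being statistically redundant with marks like H3K9me3),
and at bivalent promoters the H2A.Z histone variant flips H3K4me3 from the
strongest activating signal into a hallmark of low expression. `epitree`
resolves these by discovering **latent regulatory classes**: a binary
decision tree whose leaves are ordinary linear expression models over
disjoint gene sets and whose internal nodes are unsupervised
categorisation thresholds on one score column each.

## The model

Gene-level scores: for gene *i* and histone mark *j*, the score is the
constrained sum of tags

> a<sub>ij</sub> = Σ<sub>k</sub> g<sub>k</sub>,

counting ChIP-seq reads whose 5′ end, shifted ±73 bp by strand to the
modified nucleosome's centre, lies within 2000 bp of the TSS
(half-open window, 0-based coordinates). Promoter methylation is
summarised from RRBS per-CpG counts by one of four scores (SMFS, MMFS,
MMFR, SMRR); MMFS — the mean methylation fraction over assayed CpGs — is
the default and the strongest correlate of silencing.

Expression is fit on the arsinh scale (log-like, but defined at zero RPKM,
so no pseudo-count):

> sinh⁻¹(y<sub>i</sub>) = μ + Σ<sub>j</sub> β<sub>j</sub> x<sub>ij</sub> + ε<sub>i</sub>,

scored by adjusted R² (in-sample, 10-fold CV, or replicate holdout).
Putative regulatory roles are the loadings of the principal component of
sinh⁻¹(**A**) = **UΣV**ᵀ most predictive of expression, sign-oriented so
positive = activator-like. The decision tree selects each categorisation
threshold γ by scanning the empirical quantiles of the split column and
maximising the cumulative Δadjusted-R² of the two child models over a
genome-wide baseline, optionally calibrated against models built from
randomly sampled gene sets of equal size (a null centred on zero whose SE
shows the variation expected by chance). All tree structures over a
variable set can be enumerated and ranked exhaustively.

A matched synthetic-data generator plants four promoter classes
(methylation-silenced, bivalent H3K4me3+H3K27me3+H2A.Z, active, and
Polycomb-like repressed) with class-conditional expression, and emits
BED/TSV files whose re-scoring reproduces the generator's internal truth
exactly — every stage is testable without external downloads.

## Worked example

```r
library(epitree)

ds    <- simulate_dataset(synthetic_config(n_genes = 2000, seed = 42))
paths <- write_dataset(ds, "sim")           # BED6 tags, RRBS TSV, expression TSV

genes <- read_tss_annotation(paths[["annotation"]], "bed6")
cfg   <- scoring_config(meth_method = "MMFS")
marks <- c("H3K4me3", "H3K27me3", "H3K9me3", "H2A.Z")
A     <- build_score_matrix(genes,
           setNames(lapply(paths[paste0("tags_", marks)], read_tag_file), marks), cfg)
mmfs  <- methylation_score(genes, read_rrbs(paths[["methylation"]], "simple"), cfg)
A     <- naive_augment(A, mmfs$score, "MMFS")
y     <- read_expression(paths[["expression"]], 1)$rpkm

fit_linear(A, y)
#> arsinh-linear expression model
#>   n = 2000 genes, 5 predictor(s) (arsinh-transformed)
#>   mu = 4.6912, adj R^2 = 0.7719
#>  H3K4me3 H3K27me3  H3K9me3    H2A.Z     MMFS 
#>   0.4749  -0.9315  -0.0917  -0.2985  -1.6495 

derive_roles(pca_decompose(A[, marks]), y)
#> regulatory roles from PC2 (adj R^2 = 0.4671)
#>  H3K4me3 H3K27me3  H3K9me3    H2A.Z 
#>   0.2786  -0.9253   0.1163  -0.2294 

fit_tree(A, y, "(MMFS:(H2A.Z:H2A.Z-|H2A.Z+)|MMFS+)")
#> decision tree of expression models
#>   structure: (MMFS<=0.6086:(H2A.Z<=30:H2A.Z-|H2A.Z+)|MMFS+) 
#>   baseline adj R^2 = 0.7719 (H3K4me3, H3K27me3, H3K9me3, H2A.Z, MMFS)
#>   cumulative adj R^2 = 0.8774 (delta = +0.1055)
#>   class n_genes genes_pct    adj_r2 delta_adj_r2
#>  H2A.Z-     679        34 0.8808995   0.03023536
#>  H2A.Z+     501        25 0.8127358   0.05372518
#>   MMFS+     820        41 0.2243604   4.42284408
```

Reading the output: the genome-wide model explains 77% of arsinh-RPKM
variance; H3K4me3 carries a positive (activator-like) coefficient and
loading, H3K27me3 a negative one. The tree's unsupervised thresholds
(MMFS ≤ 0.61, H2A.Z ≤ 30 tags) recover the planted classes — 41% of genes
land in the methylated class `MMFS+` — and the concatenated class models
lift the cumulative adjusted R² by +0.11 over the same-data baseline, the
signature of genuine conditional structure. (The huge `MMFS+`
delta_adj_r2 reflects how badly a genome-wide model describes near-silent
genes, whose class model is honestly weak but unbiased.) Per-gene labels
come from `assign_classes()`; `write_class_assignments()` exports them.

A command-line wrapper with `simulate`, `score`, `fit`, `roles`,
`evaluate`, `tree` and `search` subcommands is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/epitree.R", package="epitree"))')" \
  tree --scores scores.tsv --expression expr.tsv \
  --structure "(MMFS:(H2A.Z:H2A.Z-|H2A.Z+)|MMFS+)" --out out/
```

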