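---
title: "Methods: from single-cell DRG expression to chronic-pain heritability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from single-cell DRG expression to chronic-pain heritability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paincell)
```

## The problem

Somatosensory neurons in the dorsal root ganglion (DRG) fall into
transcriptomic types (PEP, NP, TH-like, and so on). Two questions arise
when such single-cell atlases meet human genetics of chronic pain:

1. **Identity**: how confidently can a cell (possibly from another
   dataset, platform, or species with genes renamed to orthologs) be
   assigned to a reference cell type?
2. **Heritability**: do common-variant associations for chronic-pain
   phenotypes concentrate in genes that are specific to particular
   neuronal types?

`paincell` implements the computational chain for both questions, plus a
synthetic-data module that generates every input with the statistical
structure the analysis assumes, so the whole chain is testable without
restricted primate or biobank data.

## Cluster specificity (the gene-selection front end)

Raw counts are depth-corrected with strict median-of-ratios size
factors: factor_j is the median over genes (with positive geometric mean
across samples) of count_gj / geomean_g. Factors are meaningful up to
the shared geometric-mean reference, so doubling one sample's reads
exactly doubles its factor *relative to the others*. If no gene is
expressed in every cell the estimator is undefined and
`estimate_size_factors()` refuses to guess (no pseudo-reference
fallback); deeply sequenced data always contain ubiquitous genes.

For a cluster *c*, each gene is scored by ordinary least squares of
transformed expression on a membership indicator (in = 1, out = 0) with
sex as a covariate. Two open choices are both implemented and
documented rather than asserted:

* **Transform**: the default regresses `log1p(counts / size_factor)`;
  the log stabilizes the strong mean-variance relation of counts and
  makes the toy oracle used in the tests exactly reproducible. A raw
  scale fit is available via `log_transform = FALSE`.
* **Size factors**: the default pre-divides counts; alternatively
  (`sf_mode = "covariate"`) `log(size factor)` enters the design matrix
  and raw counts are transformed directly.

Genes are ranked by decreasing membership t-statistic; ties break on
ascending gene id so output is identical across platforms. The "top
fraction" rule retains `round(q * n_genes)` genes (half away from zero,
minimum 1); with q = 0.10 a 13,220-gene universe yields exactly 1322.
A gene constant across cells has no residual information; its t is
defined as 0 (or ±Inf for a perfectly separating gene), so degenerate
fits never float to the top by numerical accident.

Marker panels for the classifier come from `rank_markers()`:
over-dispersed genes (CV² above the median-CV² trend of their
mean-expression bin, 20 bins) ranked by the average of a fold-change
rank and an "enrichment score change" rank. The latter is our stand-in
for a heuristic cited without restatement in the source literature: the
fraction of in-cluster cells expressing the gene minus the fraction of
out-cluster cells expressing it. It is exact at the extremes (1.0 for a
perfect marker) and monotone in between, which is all the panel
selection needs.

## The probabilistic cell-identity scorer

The scorer is a deliberately small feed-forward network: an input node
per marker gene, one hidden layer of ReLU units sized at 20% of the
marker count, and a softmax output over reference types. Features are
`log1p`-transformed and min-max scaled **using reference statistics
only**; query values are clipped to [0, 1]. Scaling is guarded against
double application (min-max is not idempotent).

Training minimizes cross-entropy by minibatch SGD with Nesterov
momentum (gradients at the look-ahead parameters), 30% inverted dropout
on the hidden layer, and scaled-uniform fan-in weight initialization.
Everything is a pure function of the seed, so identical calls give
bit-identical weights.

Defaults and their reasons:

| parameter | default | why |
|---|---|---|
| hidden width | `round(0.2 × markers)`, min 4 | the 20% rule targets panels of ≥ 20 markers; below 4 units, 30% dropout regularly removes half the layer's capacity and training stalls at chance |
| dropout | 0.30 | regularization against overfitting small references |
| learning rate / momentum | 0.1 / 0.9 | stable on [0,1]-scaled features across the test grid |
| batch size | 64 | full-batch for small references, bounded memory for large |
| epochs | 100 (max) | early stopping usually ends sooner |

The learning-rate/epoch/momentum choice is, in manual practice, read
off a learning curve; `cross_validate()` automates that with early
stopping: training halts when held-out accuracy has improved by less
than 0.001 for 20 consecutive epochs. Accuracy is reported by
stratified 3-fold cross-validation (every class appears once per fold).

**Permutation significance.** The statistic for a (query cluster,
reference type) pair is the mean predicted probability of the type over
the cluster's cells. The null retrains the scorer on label-shuffled
references B times — a dataset-level permutation; shuffling the
reference rather than the query is an interpretive choice, recorded
here, that makes the null "no association between reference expression
and labels". The p-value uses the add-one rule
p = (1 + #{null ≥ observed}) / (B + 1), so p ∈ (0, 1] and an observed
value beating all of B = 99 nulls gives p = 0.01 exactly.
Benjamini–Hochberg adjustment runs across all pairs. B below 19 is
refused; below 99 warned.

`radar_embed()` summarizes a probability row as a point in a regular
polygon, one vertex per reference type (first vertex at 90°,
counter-clockwise, unit circle): the probability-weighted vertex
combination. One-hot rows land on their vertex, uniform rows at the
centroid, and every point stays in the convex hull.

## The gene-area statistic and its Bessel null

For genes shared between a cluster's specificity table and a gene-level
GWAS table (e.g. MAGMA output), the "area" a gene spans in the
specificity-by-GWAS scatter is the signed product
`area = z_cell × z_gwas`, with `z_cell` the membership t-statistic and
`z_gwas` the supplied gene-level z. Genes with non-positive specificity
are excluded — negative specificity means depletion in the cell type,
which is not the hypothesis — and the count of exclusions is attached
to the result.

If both scores were independent zero-mean normals with scales s₁ and
s₂, their product would have the density

f(z) = K₀(|z| / σ) / (π σ),  σ = s₁ s₂,

where K₀ is the modified Bessel function of the second kind, order 0.
This density integrates to exactly 1 (∫₀^∞ K₀ = π/2). We fit the single
scale σ by maximum likelihood with a bounded 1-D search (tolerance 10⁻⁶
on σ); location is fixed at 0 by symmetry, because a location parameter
is not identifiable from a symmetric product null and nothing in the
model motivates one. Areas exactly equal to 0 sit on the log-singularity
of K₀ and are excluded from the fit with a warning (they are a
measure-zero event for continuous inputs).

The p-value of a gene is the one-sided tail
p = ∫_{−∞}^{−|area|} f(z) dz, computed by adaptive quadrature (absolute
tolerance 10⁻¹⁰) with the integration domain split at σ so the
singularity at zero is confined to one panel. No doubling is applied:
p ∈ (0, 0.5], p(0) = 0.5 exactly, and p decreases strictly in |area|.
Under a true product-normal null the p-values are uniform on (0, 0.5]
(so P(p ≤ t) = 2t), which the calibration test checks after σ is
fitted. Genes up to BH-FDR 20% feed the pathway stage.

## Pathways, annotations, design bookkeeping, meta-analysis

**Pathway overrepresentation** is the hypergeometric upper tail
P(X ≥ k) including the observed overlap — the standard
overrepresentation convention. Pathways are tested only if their size,
*after* intersection with the analysis universe, lies in [10, 1000]
(both bounds inclusive). The universe defaults to the genes that
entered the gene-area analysis (expression ∩ GWAS universe) rather than
the whole genome: enrichment is then relative to what could have been
detected, and the choice is configurable.

**Annotation tracks** for partitioned heritability flag every SNP whose
position falls in [start − window, end + window) of any gene in a set
(0-based half-open coordinates throughout; window default 100 kb,
configurable). Overlapping genes flag a SNP once. A caller-supplied
control gene list yields a control track built identically. The
stratified LD-score regression itself is external; its per-annotation
coefficient estimates and standard errors are consumed from TSV.

**Leave-one-site-out design**: to control pain-site comorbidity, each
site's GWAS is re-run once per other site with comorbid cases removed —
all ordered pairs, n² − n runs, 56 for eight sites. The
**effective minor-allele count** sanity check is the plain product
MAF_min × INFO_min × n × ploidy (0.001 × 0.9 × 163,835 × 2 ≈ 295).

**Meta-analysis** across phenotypes is fixed-effect inverse-variance
pooling (weights 1/se²; pooled se = (Σw)^{−1/2}; two-sided normal p):
k identical estimates pool to (β, se/√k), and the implementation is
cross-checked against an independent fixed-effect routine in the tests.

## What the synthetic data does and does not emulate

`simulate_counts()` draws negative-binomial counts (variance
μ + μ²/θ, θ = `nb_dispersion`) with disjoint per-cluster marker
programs multiplied by `marker_fold_change` in their home cluster,
log-normal per-gene baselines with a tail of ubiquitous high-expression
genes (so strict size-factor estimation is well-posed, as in deeply
sequenced DRG data), log-normal per-cell depth, cells cycled over
animals with configurable sexes, animals alternating between two
platforms, and optional per-animal or per-sex log-scale shifts
(default 0) for deliberately confounded datasets. Defaults — 4 clusters
× 50 cells, 2000 genes, 20 markers per cluster, fold change 8,
θ = 2, depth sigma 0.3 — are desk-scale study conditions under which a
specificity regression recovers essentially all true markers in the top
decile and a 3-fold cross-validated scorer reaches ≥ 0.95 accuracy;
null configurations (fold change 1, `causal_shift` 0) drive the
false-positive-rate tests.

`simulate_gwas_gene_stats()` draws gene z-scores N(0,1), shifted by
`causal_shift` for a designated causal set — a stand-in for gene-level
GWAS summary output, not for individual-level genotypes.
`simulate_pathways()` and `simulate_snp_map()` provide uniform gene
sets and toy coordinates.

Not emulated: reads/UMIs, ambient RNA, doublets, batch structure beyond
scalar log-shifts, linkage disequilibrium between SNPs, correlated gene
blocks, or realistic minor-allele-frequency spectra. Passing tests
therefore certify the *computational chain* — selection rules, null
distributions, error control, determinism — not robustness to every
artifact of real data.

## Numerical choices and degenerate inputs

* Top-fraction size: round half away from zero, minimum 1; boundary
  ties resolved by (t descending, gene id ascending).
* Exact-fit regression genes: residual variance below 10⁻²⁰ of the
  response scale marks an exact fit; t is then 0 (null coefficient) or
  ±Inf (perfect separator), never a ratio of rounding errors.
* Bessel quadrature split at ±σ; likelihood uses exponentially scaled
  K₀ so large |z|/σ stays finite; p floored at 10⁻³⁰⁰.
* `fit_bessel_null()` needs ≥ 50 non-zero areas and refuses degenerate
  (zero-spread) input.
* Problem sizes in the test suite: 10⁴ simulated areas for scale
  recovery, a 10⁷-draw Monte-Carlo tail oracle, 200 cells × 2000 genes
  per simulated experiment, 200 null repeats at B = 199 for the
  permutation type-I study.

## Known limitations

* The membership regression is OLS on transformed counts, not a count
  GLM; with very low counts its t-statistics are only approximately
  normal. The product-normal null absorbs most of the miscalibration,
  and the calibration test bounds what remains under the null.
* The scorer's permutation test retrains B times; for large references
  that is the pipeline's dominant cost, and B trades granularity
  against time.
* Cross-species use assumes orthologs are already renamed to a shared
  gene namespace; no sequence-based orthology is performed.
* The heritability regression (stratified LD-score) and the gene-level
  GWAS model (MAGMA) are consumed, not implemented; conclusions about
  their internals are out of scope.
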