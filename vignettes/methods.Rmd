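---
title: "Models, parameters and design choices in scmalig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in scmalig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

scmalig implements the numerical core of a single-cell tumor analysis for
gut adenocarcinoma cohorts. This vignette explains each model, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the design decisions taken where the workflow left real
freedom. It states no empirical claim that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Quality control and normalization

Cells are kept when they exceed a minimum number of detected genes and
total transcripts and stay below a maximum mitochondrial fraction, all
with *strict* inequalities — a literal reading of "more than / lower
than". Two presets reflect the two capture chemistries the workflow is
designed around: `"strt"` (plate-based, deep: > 1000 genes, > 10,000
transcripts, < 20% mitochondrial) and `"tenx"` (droplet-based, shallow:
> 500, > 1000, < 50%). Mitochondrial genes are recognized by the `MT-`
name prefix.

Normalization is the standard library-size log transform
`log(1 + s · x / total)` with natural log and scale factor `s = 1e4` by
default. Neither the base nor the scale is dictated by the workflow
itself, so both are arguments; per cell, `sum(exp(value) − 1) = s`
exactly, which the tests assert to 1e-6 relative.

Clustering is a contract, not a contribution: a k-nearest-neighbor graph
(Euclidean distance on the top 20 principal components, k = 15) with
Louvain communities. The malignant caller needs stable labels; any
community algorithm with a resolution knob would do. All-identical input
short-circuits to a single cluster rather than letting modularity
optimization invent structure in ties.

## 2. Copy-number inference and the malignancy call

The smoother follows the classic expression-to-copy-number recipe:

1. subtract the per-gene mean of the reference cells (normal epithelium
   from adjacent tissue) in log space;
2. clamp residuals to ±`cap` (default 3) so single outlier genes cannot
   mimic an amplification;
3. moving average of width `window_size` (default 101 genes, the
   convention this family of tools ships with) along each chromosome,
   with a symmetric window that shrinks near chromosome ends — dropping
   telomeric genes would discard exactly the regions arm-level events
   live in;
4. subtract each cell's median (removes per-cell baseline shifts);
5. re-center so the reference mean is 0 per gene;
6. exponentiate, giving ratios with baseline 1.

Chromosomes with fewer positioned genes than the window (for the
synthetic genome, the mitochondrial contig) are dropped with a warning.

The malignancy score is the mean of squared deviations from copy-neutral,
`MSD(c) = mean((cnv − 1)²)`, computed in ratio space by default; whether
the original procedure used ratio- or log-space residuals is not
documented, so `space = "log"` is available. The threshold is the 90th
percentile of the reference cells' scores, computed by linear
interpolation between order statistics (R's type-7 quantile) — pinned so
tests can be exact. By construction ~10% of held-out copy-neutral cells
exceed it; the acceptance suite checks 10% ± 3 points on null cohorts.

The final call is per cluster: a cluster is malignant when the fraction
of high-CNV cells exceeds `dominance` (default 0.5). The original
workflow made this judgment manually; a fixed majority rule trades
curation for reproducibility, and the fraction is an argument.

## 3. Expression programs and meta-programs

Per patient, candidate signatures come from two routes run on the
malignant cells only:

* **PCA poles** — the `n_genes_per_pole` (50) most positive and most
  negative loadings of each of the top `n_components` (6) principal
  components. How many PCs and genes per pole the original analysis used
  is unstated; both are arguments.
* **NMF factors** — multiplicative-update NMF (Frobenius loss) on
  *relative* expression: per-gene centered, negatives clipped to zero.
  On raw log expression the leading factors reproduce the mean
  expression profile instead of programs (observed directly during
  development: planted-program Jaccard < 0.1 raw vs ≈ 0.8 centered).
  Initialization is deterministic NNDSVDa; random restarts recovered
  planted programs unreliably. `center = FALSE` and `init = "random"`
  remain available, and the rank-1 exactness test runs uncentered.

Signatures are scored on all malignant cells with the control-bin module
score, correlated (Pearson), and hierarchically clustered with average
linkage on 1 − r. A cluster whose members span at least two patients is
a *shared* meta-program. The cut is `k = 12` by default — deliberately
deeper than the number of expected programs, because at small k the
noise signatures (residual NMF factors, weak poles) are absorbed into
program clusters and dilute their consensus; surplus clusters are
harmless since non-shared singletons are ignored. The consensus list
keeps genes supported by ≥ 2 members (`min_support`), ranked by support
and capped at the member signature size so that one large mixed cluster
cannot flood the consensus.

Cells are assigned to the argmax meta-program module score, ties broken
by program order. On the synthetic progression path the planted argmax
is genuinely ambiguous for cells near the path's two branch points
(weight margins < 0.2); recovery claims are therefore checked on
decisive cells, with a looser bound overall.

## 4. Gene-set scoring and differential expression

The module score bins all genes into `n_bins = 24` expression-matched
bins and samples `n_ctrl = 100` control genes (with replacement) per
signature gene; the score is mean(signature) − mean(controls) per cell.
Both defaults follow the convention of the widely used implementation
this replaces; neither is documented in the original workflow. The
single-sample enrichment score ranks genes within each cell and sums the
difference between the rank-weighted (`rank^0.25`) in-set ECDF and the
unweighted out-set ECDF; it depends on ranks only, hence is invariant
under strictly monotone per-cell transforms (asserted to 1e-9).

Differential expression is a per-gene two-sided Wilcoxon rank-sum test
after two pre-filters: detection in ≥ 25% of either group and
|log fold change| ≥ log 2, with the fold change computed as
`log(mean(expm1(x)) + 1)` per group — the pseudo-count dialect had to be
pinned for exact tests and is configurable. Correction is Bonferroni at
α = 0.01 (the workflow's stated choice for this step), with BH
available. Exhaustion-style stratification splits at the median (ties to
the low group); the original split rule is unstated, so a fixed
threshold rule is also provided and the all-equal case errors rather
than inventing a split.

## 5. Ligand–receptor edges

For each ligand–receptor pair and ordered (sender, receiver) type pair:
weight = mean ligand expression in sender × mean receptor expression in
receiver ("mean method"); detected requires ≥ `detection_threshold`
(0.2) expressing cells on both ends, where "expressing" means
normalized value > 0 (the UMI dropout convention); specificity is the
product of the sender's share of the ligand mean and the receiver's
share of the receptor mean across types, so it sums to 1 per pair
(asserted to 1e-9). Differential edges across ordered conditions use
log weight ratios with a pseudo-weight of the smallest nonzero weight ×
1e-3 for zeros; "continuously up/down" requires strict monotonicity at
every step. The proprietary pair database is not bundled; pairs come
from a two-column CSV.

## 6. Drug-response prediction

Malignant and normal cells are each split into `n_groups = 50` random
near-equal pseudo-bulk groups (the only reading under which the stated
tumor-vs-normal t-test is computable), profiled as per-gene means. The
tumor score — never defined in the original workflow — is the module
score of the malignant-vs-normal differential expression signature on
the pseudo-bulk profiles, a stated proxy.

Per drug, a ridge regression (glmnet, α = 0, intercept unpenalized) is
fit on the cell-line panel with the penalty chosen by 5-fold
cross-validation over an explicit broad grid (1e3…1e-6): glmnet's
automatic path stops once deviance saturates, which strands the CV
optimum at the path edge on strong-signal panels. Harmonization is per
gene: the default `"double"` mode standardizes training lines by
training statistics and pseudo-bulks by pseudo-bulk statistics, mapping
the two clouds onto a common location and scale — a deterministic
stand-in for the quantile homogenization used by cell-line transfer
tools. One-sided standardization (`"train"`, with a ±3 SD clip) is kept
for same-platform prediction, where it is exact. Candidates must pass
all three filters: BH-adjusted t-test p < 0.05, log₂(mean tumor AUC /
mean normal AUC) < −0.1, and Pearson correlation with the tumor score
< −0.5. BH is used (the workflow leaves this correction unqualified,
unlike its Bonferroni-qualified DEG step); Bonferroni and Spearman are
arguments. Drugs with non-positive mean predicted AUC are excluded with
a warning, since the log ratio is undefined.

## 7. The synthetic world

`generate_cohort()` draws UMI counts from a gamma-Poisson (negative
binomial) model: lognormal per-gene base abundances (the mitochondrial
budget pinned at 8% of expression so QC has something to filter),
per-cell library sizes lognormal around 20,000, shared dispersion 0.3 —
typical UMI overdispersion. Every cell has an epithelial cell of origin
(three types with 3× marker blocks); malignant cells additionally carry
(i) a uniformly upregulated marker block scaled by `exp(program_loading)`,
(ii) chromosome-level CNV multipliers (default: two 1.5× gains per
patient), and (iii) four disjoint 50-gene programs whose weights follow
a piecewise-linear simplex path along a latent progression axis — cell
cycle at the start, mitochondria in the middle, branching into
metabolism or EMT — with `exp(weight × loading)` boosts, loading 0.8.
Because all planted effects scale with the loading and the CNV table, a
zero-loading, zero-CNV config yields malignant and normal cells drawn
from identical distributions: the null world downstream false-positive
checks run on.

`generate_drug_panel()` draws cell lines from the same model (no CNVs,
no origin types) over the *full* gene universe — normalization totals
must match the cohort's — and reports an `n_genes` subset containing the
program genes. Gene base abundances are a deterministic function of the
config, shared between cohort and panel: relative abundance is a
property of the transcriptome, and independently redrawn abundances
made panel-abundant targets cohort-rare, which no harmonization can
repair. Lines carry four *independent* U(0,1) program activities rather
than simplex weights; simplex weights make any target readout a
difference of collinear directions whose transfer contributions cancel
on pseudo-bulks. Planted-sensitive drugs respond as
`AUC = intercept + β · mean(target expression) + N(0, noise_sd)` with
β = −1, noise 0.02 and intercept 2.1 by default, giving baseline AUC
≈ 0.7 and strictly positive responses; targets default to broad
staggered windows covering half of each program (~100 genes), so a
drug's readout tracks overall malignant program activity — small
single-program readouts produce true log-fold-changes that sit on the
candidate filter's own threshold (measured as weak as −0.04, where a
perfect estimator fails) and drown in the progression-mix heterogeneity
of tumor pseudo-bulks.

What the generator does **not** emulate: batch effects requiring
integration, doublets, ambient RNA, patient-specific baseline shifts,
immune and stromal compartments, and realistic gene–gene correlation
beyond the planted blocks. A green test therefore establishes that the
implementations compute their definitions correctly and recover planted
structure at realistic noise — not that the pipeline is robust to
artifacts it never sees.

## 8. Numerical and degenerate-input choices

Quantiles: type-7 interpolation everywhere. NMF: NNDSVDa init, 200
multiplicative updates, convergence on relative loss change < 1e-6,
factors scaled to unit column norm. Constant expression collapses the
module-score binning to one bin; all-zero program scores fall back to
the first program with a message; empty QC results, empty reference
sets, zero-total cells, mismatched sidecars and out-of-range config
values all raise immediate errors. Pipeline outputs are deterministic
given config and global seed (stage seeds are derived arithmetically);
the JSON run record contains wall-clock timestamps and is excluded from
byte-identity comparisons.

## 9. Known limitations

Clustering quality on real data depends on preprocessing not modeled
here (HVG selection, integration). The moving-average CNV proxy cannot
separate copy number from dense regulatory programs on the same arm —
the reason the synthetic programs are spread across chromosomes. The
dominance rule replaces expert curation and will mislabel clusters that
mix malignant and normal cells at near-equal rates. Ridge transfer is
only as good as the harmonization; the double standardization assumes
the group-level covariance structure resembles the line-level one and
is a pluggable choice, not a solved problem.
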