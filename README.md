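# scmalig

Single-cell analysis of gut adenocarcinoma cohorts: malignant-cell calling
from expression-inferred copy number, intra-tumor expression meta-programs,
gene-set scoring, ligand–receptor interaction screening, and
ridge-regression drug-response prediction — with a synthetic-cohort
generator carrying planted ground truth so every stage can be validated
end to end without access to patient data.

## Who this is for

Computational biologists who want the bespoke numerical steps of a
single-cell tumor study as tested, reusable R functions rather than a
pile of scripts: given UMI count matrices with tumor/normal annotation,
the package separates malignant from normal epithelium, extracts the
recurring expression programs of the malignant compartment, quantifies
ligand–receptor signaling between compartments, and transfers cell-line
drug-response models onto pseudo-bulk profiles to nominate candidate
compounds.

## The methods in brief

* **Copy-number inference and malignancy calling.** Log-normalized
  expression is centered on a normal-epithelium reference, clamped,
  smoothed with a moving average along each chromosome (window *w* = 101
  genes), median-centered per cell and re-referenced, giving a relative
  copy-number profile with baseline 1. Each cell's malignancy score is
  the mean of squared deviations, MSD(c) = mean over genes of
  (CNV(c,g) − 1)²; cells above the 90th percentile of the reference
  scores are "high-CNV", and a cluster is called malignant when high-CNV
  cells exceed half of its membership.
* **Meta-programs.** Per patient, candidate programs are the positive and
  negative poles of the top principal components plus NMF factors of the
  malignant cells' relative expression; signatures are scored per cell
  (control-bin module score), correlated (Pearson), hierarchically
  clustered (average linkage, distance 1 − r), and clusters spanning ≥ 2
  patients become shared meta-programs with a support-ranked consensus
  gene list.
* **Scoring.** Control-bin module scores (expression-matched control
  genes) and a rank-based single-sample enrichment score (weighted ECDF
  difference, exponent α = 0.25); Wilcoxon differential expression with
  detection (min.pct = 0.25) and fold-change (log 2) pre-filters and
  Bonferroni/BH correction.
* **Ligand–receptor edges.** weight = mean ligand expression in the
  sender type × mean receptor expression in the receiver type; an edge
  counts as detected only if ≥ 20% of sender cells express the ligand and
  ≥ 20% of receiver cells the receptor; specificity is the product of the
  sender's and receiver's share of the respective means and sums to 1
  over type pairs.
* **Drug prediction.** Malignant and normal cells are split into 50
  random pseudo-bulk groups per class; per drug, a ridge regression
  (cross-validated penalty) trained on a cell-line panel predicts each
  group's AUC after per-gene harmonization; candidates must satisfy
  adjusted p < 0.05 (t-test, tumor vs normal groups), log₂FC < −0.1 and
  Pearson correlation with the tumor score < −0.5. Lower AUC means more
  sensitive.

## Worked example

```r
library(scmalig)

co  <- generate_cohort(cohort_config(seed = 7))   # 2 patients x 300 cells
cts <- qc_filter(co$counts, qc_thresholds(preset = "tenx"))
ex  <- normalize_log(cts)
cl  <- cluster_cells(ex, seed = 3)
ref <- ex$cell_ids[ex$cell_meta$tissue == "normal"]
cnv <- infer_cnv(ex, co$positions, ref)           # drops chromosome MT
sc  <- msd_score(cnv)
thr <- malignancy_threshold(sc[ref], 90)
call <- call_malignant(sc, thr, cl)
table(truth = co$truth$cells$class, call = call$final_call)
#>            call
#> truth       malignant normal
#>   malignant        60      0
#>   normal            0    540
```

All 60 planted malignant cells (two 1.5× chromosome gains plus four
expression programs) are recovered with no false positives: sensitivity
and specificity are both 1 on this cohort.

The same cohort drives the downstream stages; `run_pipeline()` (or the
`exec/scmalig` CLI: `scmalig simulate`, `scmalig run --config cfg.yaml`)
chains QC → clustering → CNV → programs → scoring → edges → drug
prediction from one YAML config with a single global seed, and writes
plain-text outputs plus a JSON run record.

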