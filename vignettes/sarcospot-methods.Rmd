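---
title: "sarcospot: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sarcospot: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcospot)
```

sarcospot implements an integrative biomarker-discovery workflow for
undifferentiated sarcoma (US), a family of aggressive mesenchymal cancers
with few established molecular markers. The workflow crosses three lines of
evidence — bulk tumor-versus-normal differential expression, cell-line
expression ranking, and spatial single-cell copy-number structure — and
intersects them with membrane-localization evidence to nominate cell-surface
biomarker candidates. Every stage is driven by a synthetic-data module with
known ground truth, so the whole pipeline is testable offline.

This vignette explains each stage's model and assumptions, the tunable
parameters, the numerical conventions, and the design decisions taken where
the method left genuine freedom. No empirical claims are made here beyond
what the package's own test suite and acceptance script compute.

## Bulk differential expression

**Quality control.** Genes are retained when FPKM ≥ 1 (parameter
`min_fpkm`) in at least 20% of all samples (`min_frac`), or in at least 20%
of samples within the tumor or the normal group, where a group clause is
only consulted when the group has at least `min_group_size = 2` samples.
The analysis is then restricted to protein-coding genes (`coding_only`).
The floor comparison is inclusive (`>=`), so a gene at exactly FPKM = 1
counts as expressed while 0.99 does not.

**Model.** Expression is modeled on the `log2(FPKM + 1)` scale. For each
gene a two-group linear model is fit (unpaired; the cohort design gives no
pairing of tumors to normals, so none is modeled). Residual variances are
shrunk toward a common prior by the standard empirical-Bayes scheme: writing
$e_g = \log s_g^2 - \psi(d/2) + \log(d/2)$ with residual df $d$, the prior
df $d_0$ solve $\psi'(d_0/2) = \operatorname{Var}(e) - \psi'(d/2)$
(Newton iteration on the trigamma function; divergent when the observed
spread of variances is already explained by chi-square noise, in which case
every posterior variance collapses to the common prior variance), and the
posterior variance is the df-weighted mix
$(d_0 s_0^2 + d s_g^2)/(d_0 + d)$. The moderated t statistic is referred to
a t distribution on $d + d_0$ df, p-values are two-sided, and multiplicity
is handled by Benjamini–Hochberg (`stats::p.adjust`; the test suite checks
it against a brute-force step-up with cumulative minimum).

**Classification.** A gene is called up- (down-) regulated when
`fdr < 0.01` and `log2fc >= 2` (`<= -2`). The log2 threshold of 2 is used
inclusively; it corresponds to a linear fold change of 4. The log2 fold
change is the difference of group means of `log2(FPKM + 1)`, i.e. the
transform is applied before modeling, not to a ratio of mean FPKM.

## Pathway scoring (GSVA)

Single-sample pathway activity uses the gene set variation analysis
statistic with a Gaussian kernel. Per gene, the cross-sample cumulative
distribution is estimated at the observed points with bandwidth
`sd / kernel_bandwidth_factor` (default divisor 4); genes with zero
cross-sample variance receive the uninformative value 0.5. Within each
sample, genes are ranked by this statistic and a weighted random walk is
run down the ranking for each gene set: set genes step up with weight
$|p/2 - \text{rank}|^\tau$ (default $\tau = 1$) normalized within the set,
other genes step down by $1/(p - m)$. Two score variants are implemented
behind the `method` switch: the default `"mx_diff"` (maximum positive
deviation minus the magnitude of the maximum negative deviation, the
published method's default) and `"max_abs"`. Scores are bounded in
$[-1, 1]$; when every gene ties on the kernel statistic the ranking carries
no information and all scores are defined as 0.

Before scoring, gene sets are intersected with the tumor-upregulated,
expressed genes; sets retaining fewer than 10 genes are excluded (a set
retaining exactly 10 is kept). Differential pathway activity reuses the
moderated two-group test on the score matrix at FDR < 0.05, and row-wise
z-scores are emitted for heatmap display only.

## Quadrant spotlight integration

Two datasets without shared normalization factors are put on comparable
scales by (i) ΔNT, the tumor median minus normal median of
`log2(FPKM + 1)` per gene, and (ii) within-sample ECDF percentiles of the
cell-line values computed across a fixed gene subset (the DEG list), where
the percentile of a gene is its midrank among the subset divided by the
subset size — values lie in $(0, 1]$ and ties share midranks, which makes
the no-ties mean percentile exactly $(n+1)/2n$. Each gene is summarized by
its median percentile across cell-line samples.

Selection takes genes with ΔNT strictly positive (a zero difference is
excluded) whose median percentile is at or above the empirical 80th
percentile of the median percentiles across the records. The quantile uses
linear interpolation of order statistics (R's default type 7). Two
readings of the criterion were possible — a fixed 0.8 percentile value, or
the 80th percentile of the observed medians; the latter is implemented
because with 101 distinct records it yields a threshold at the 81st order
statistic and exactly 21 selected genes, matching the documented selection.
The x-axis criterion is interpreted as ΔNT > 0 (the axis is ΔNT; the
fold-change wording refers to the same tumor-minus-normal direction).

## Spatial preprocessing

Per-cell quality control retains cells that lie in the selected fields of
view, are CD45-negative (default threshold: Otsu split of the observed
CD45 intensity histogram, overridable), have at least 20 detected genes,
and are flagged singlets. Doublet detection itself is not re-implemented:
flags are consumed as input (from the generator, or any external tool).

Counts are normalized to counts per million and `log1p`-transformed;
optional TMM factors treat each cell as a library (reference = the cell
whose upper-quartile expression is closest to the mean upper-quartile;
per-cell factor = precision-weighted mean of M values after trimming 30%
of M and 5% of A two-sidedly; factors centered to log-mean zero). The test
suite checks the factors against the reference implementation in edgeR to
10 decimal places.

Clustering scales each gene, takes `n_pcs = 30` principal components,
removes batch structure by centering each batch's mean in PC space — a
deliberately linear surrogate for published batch-integration algorithms,
which are external contributions and out of scope — and clusters by
Louvain community detection on a shared-nearest-neighbor graph (Jaccard
weights, pruned below 1/15), or by k-means when a cluster count is forced.
Cells are processed in canonical id order so the partition is exactly
invariant to input row permutation. The SNN neighborhood (`snn_k`,
default 15) behaves like a resolution control: neighborhoods on the order
of the expected population size avoid splitting well-separated groups.

## Two-pass self-referencing CNV inference

The expression-based CNV signal for a cell is the log2 ratio of its
`log1p` CPM to a baseline profile, clamped to ±3 log2 units, averaged over
a 25-gene moving window along the genome within each chromosome (windows
shrink at chromosome edges), then re-centered so each cell's median ratio
is zero. The window default of 25 genes reflects the 1000-gene panel: the
wide windows used for whole-transcriptome data would span a third of a
chromosome here.

*Pass one* uses the tissue-mean profile as baseline and scores each cell
by its mean squared smoothed ratio (zero iff copy-neutral, quadratically
homogeneous). Reference-like cells are then selected per tissue as the
lowest-deviation fraction `f`, the smallest value in [0.2, 0.4] whose pool
reaches `min_pool = 200` cells (the upper bound if unreachable), after
excluding mitotic-high cells (mean `log1p` CPM over a configurable
cell-cycle gene list above the tissue mean + 1 sd; no list, no exclusion —
the rule mirrors the thresholding idiom used for CNV-high calls).

Because the mean-squared deviation confounds CNV signal with
depth-dependent sampling noise, the wrapper pools first-pass deviations
over each cell's 10 nearest spatial neighbors (unweighted mean, self
included) before ranking. Tumor clones are spatially coherent, so this
averages noise within clones without mixing them; the unweighted mean is
used here — rather than the distance-weighted propagation applied to final
scores — because the latter's self weight $1/\epsilon$ dominates whenever
neighbor distances are large compared to $\epsilon$, leaving exactly the
spatially isolated cells unsmoothed.

*Pass two* recomputes ratios against the mean profile of the selected
references (per tissue) and summarizes each cell by `cnv_level`, the
median inferred absolute copy number $2 \cdot 2^{\text{ratio}}$ (diploid
neutral = 2; "copy number" is read on the absolute scale), and
`cnv_score`, the upper-tail deviation from neutrality: the mean of
$|\text{ratio}|$ over the bins at or above the cell's 90th percentile of
$|\text{ratio}|$ (`upper_tail_q = 0.9`). A tail statistic is used because
a focal aberration moves only a minority of bins; the tail is robust to
the neutral majority.

Scores are optionally propagated over the `k = 10` nearest same-tissue
neighbors with weights $1/(d + \epsilon)$, $\epsilon = 10^{-3}$ mm (self
distance 0, so `k = 0` is exactly the identity), and CNV-high cells are
called per tissue as score > mean + 1 sd; a zero-variance tissue yields no
calls. Cell-type labels are never consulted anywhere in the CNV path (the
suite asserts the output is invariant under label permutation).

## Candidate prioritization

Within the target subset (CNV-high cells carrying the configured
cell-type label), genes are ranked by mean `log1p` CPM and the top 30
taken per tissue; ties break lexicographically by gene id. The cascade
intersects the per-tissue top-30 lists (per-tissue-then-intersect was
chosen over a pooled ranking because the candidates are required to be
shared between the xenograft models), then the quadrant-selected gene set,
then gates on membrane evidence. Membrane evidence is three binary
indicators (membrane association, plasma-membrane localization,
transmembrane topology) combined with weights (1, 2, 3) for display
ranking; the retained set depends only on the binary gate (default: the
membrane-association flag; the gate can be tightened to plasma-membrane
evidence or loosened to any flag), so the weights never change the
cascade outcome. Each stage can only remove genes.

## Clinical statistics

The H-score of a specimen is $\sum_{i=1}^{3} i \cdot (100 f_i)$ over
intensity fractions $f_0..f_3$, ranging 0–300; it is linear in the
fractions and invariant to cell order. Group comparisons use the Wilcoxon
rank-sum test (exact by enumeration when the combined n ≤ 12 without ties,
else normal approximation with tie and continuity corrections; a fully
tied comparison returns p = 1), Fisher's exact test on r × c tables with
the probability-ordering two-sided definition, and Pearson correlation
with the t-based p-value on n − 2 df. All three route through the base R
implementations behind the module interface; the test suite pins them to
full-enumeration oracles at small n. Survival is treated as the two-level
factor Alive vs died-of-disease; no time-to-event modeling is attempted.

## The synthetic-data module

The generators define the study conditions under which the pipeline is
tested; their defaults are fixed choices, not fitted values.

* **Bulk cohort** (`gen_bulk_cohort`): 6 tumor vs 7 normal samples, 2000
  genes, log-normal FPKM (Gaussian noise, sd 0.4, on the
  `log2(FPKM + 1)` scale), 25% of genes below the FPKM = 1 floor, 20%
  annotated non-coding, 100 up- and 40 down-regulated genes planted at
  |log2 fold change| 2.5. Planted genes are protein-coding by
  construction: the analysis discards non-coding genes, so effects planted
  there would be unrecoverable by design rather than by statistics. With
  these settings per-gene power at the |log2FC| ≥ 2 / FDR < 0.01 rule is
  high, which is what the recall ≥ 0.9 / FPR ≤ 0.01 property exercises.
* **Cell-line panel** (`gen_cellline_panel`): two samples, uniform
  baseline on the log2 scale with sd 0.5 noise; designated genes are
  upshifted by 5 log2 units, placing them in the top decile of
  within-sample percentiles.
* **Spatial tissue** (`gen_spatial_tissue`): negative binomial counts
  (size 10) with log-normal gene abundances, log-normal per-cell depth
  with mean 1500 counts over the 1000-gene panel; 0.51 mm FOVs on a grid;
  each clone a Gaussian blob (sd 0.12 mm) inside one FOV; immune cells
  (5%) scattered everywhere with high CD45 intensity (bimodal against
  tumor cells, so one threshold separates them); 2% doublets (sum of two
  cells' counts) and 2% low-depth cells with < 20 detected genes. The
  default aberrant clone (20% of tumor cells) carries a 1.5× gain over
  20% of the panel plus a one-copy loss over 10% — the complex-karyotype
  profile typical of sarcoma cell-line derivatives, and the operating
  point at which the CNV recovery properties (sensitivity ≥ 0.8,
  specificity ≥ 0.9, AUC ≥ 0.9, truth-neutral references) are exercised.
  Gene positions place the panel in order along two synthetic
  chromosomes; only the ordering matters to the smoother.
* **Clinical cohort** (`gen_clinical_cohort`): 30 patients with the fixed
  cohort composition (largest-remainder rounding, shuffled): subtypes
  23/5/1/1, grades II/III 4/26, presentation 18/7/5, survival 60/40.
  Intensity fractions are softmax-Gaussian; H-score, positivity and the
  pathologist score derive from them. The `effect` parameter shifts
  staining and cytosolic-only localization toward the deceased group; at
  `effect = 0` the groups are exchangeable, which the type-I calibration
  property (rejection rate ≈ 5% over 500 seeds) verifies.

**What the generators do not emulate.** Real CosMx data has segmentation
errors, fov-edge artifacts, cell-size-correlated capture, mouse-read
contamination in xenografts, and batch structure beyond additive shifts;
bulk FPKM cohorts have correlated genes and composition effects; none of
these are modeled. Passing tests therefore demonstrate internal
correctness of the statistics and recoverability of planted structure
under the stated noise model — not performance on real assays. In
particular, real spatial panels at lower depth or with purely focal gains
will separate less cleanly than the default simulation.

## Numerical conventions and degenerate inputs

Type-7 quantiles everywhere a quantile is taken; midranks for all rank
statistics; lexicographic tie-breaks in gene rankings; clamping at ±3
log2 units before genomic smoothing; trigamma inversion by Newton with
the standard large/small-argument closed forms; a fully tied Wilcoxon
comparison returns p = 1; constant rows z-score to 0; an all-tied GSVA
sample scores 0; a zero-variance tissue produces no CNV-high calls;
`n_pcs` above the matrix rank is capped with a warning; QC that removes
every cell or gene raises an explicit error rather than returning an
empty object.

## Problem sizes in the test suite

The suite exercises the bulk pipeline at 2000 genes × 13 samples, GSVA
oracles at ≤ 8 genes × 4 samples plus invariances at 30 × 4, the CNV
recovery band at 3000 cells × 1000 genes (single run) and 20 seeds of
1000 cells for reference purity, Wilcoxon/Fisher enumeration at n ≤ 8 and
3 × 2 tables, and 500 simulated cohorts for type-I calibration. These
sizes were chosen to make each property statistically meaningful while
keeping a full run in well under the time a contributor will tolerate.

## Known limitations

* The moderated test supports only the unpaired two-group design used
  here — no covariates, no paired models.
* GSVA is implemented for continuous log-scale expression (Gaussian
  kernel) only; there is no count-kernel variant and no competitive
  (GSEA-style) test.
* CNV inference is smoothed-expression only: no HMM segmentation, no
  subclone trees, no allele-specific events; `cnv_level` is a coarse
  summary that stays near 2 unless most of the genome shifts.
* Batch correction is a linear mean-shift surrogate; strongly nonlinear
  batch effects are out of scope.
* The Fisher test enumerates r × c tables exactly at cohort scale
  (n ≈ 30); it is not intended for large tables.
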