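---
title: "Profiling glucose-transporter metabolism of the tumor microenvironment"
author: "glutme authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling glucose-transporter metabolism of the tumor microenvironment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glutme)
```

## The model

Solid tumors are mixtures of malignant cells and infiltrating immune
cells, and the two compartments run glucose uptake through different
transporters: GLUT1 (*SLC2A1*) is the dominant transporter of cancer
cells, while GLUT3 (*SLC2A3*) is relatively enriched in immune cells.
`glutme` treats the per-sample ratio of the two transcripts,

$$\mathrm{GLUTratio} = \frac{\mathrm{CPM}_{SLC2A3} + c}{\mathrm{CPM}_{SLC2A1} + c},$$

as a surrogate of how much of a sample's glucose metabolism is carried by
the immune compartment. Downstream analyses always use
$\log_2(\mathrm{GLUTratio})$, which makes a $k$-fold shift toward either
compartment symmetric around zero. The pseudocount $c$ (default 1 CPM)
bounds the ratio when either transcript drops out; the scale on which the
ratio is taken (CPM with unit pseudocount) is a package convention —
different choices shift magnitudes but not signs or rank-based results.

Immune infiltration is summarized by a composite **ImmuneScore**: the sum
of single-sample enrichment scores of ten immune cell types (B cells,
CD4$^+$ and CD8$^+$ T cells, dendritic cells, eosinophils, macrophages,
monocytes, mast cells, neutrophils, NK cells). Enrichment per signature
is single-sample GSEA: genes are ranked by decreasing expression, and the
score is the integrated difference between the in-set cumulative
distribution weighted by $\mathrm{rank}^\alpha$ ($\alpha = 0.25$) and the
uniform out-of-set cumulative distribution. The score is a pure rank
statistic — invariant to any strictly increasing transform of the
expression vector — and no cross-sample rescaling is applied, so each
sample can be scored in isolation. Ties in expression receive average
ranks before weighting, which keeps the score independent of gene order.

A deliberate simplification: published pan-cancer work computes cell-type
enrichment with the 64-type xCell model, which layers spillover
compensation over signature scores. Here the composite keeps the stated
ten-type sum but scores each type by plain ssGSEA over compact
signatures. The composite's *construction* (a sum of per-type enrichment
scores) is preserved; its absolute scale is not comparable to xCell
output.

Two companion scores follow the same pattern: a **cytolytic score**
(geometric mean of pseudocount-shifted granzyme and perforin CPM;
defaults to GZMB/PRF1, configurable to GZMA/PRF1 since both conventions
circulate for "granzyme and perforin" activity) and a **hypoxia score**
(ssGSEA of a hypoxia signature). The hypoxia score plays a control role:
GLUT1 is a canonical hypoxia target, so hypoxia should track GLUT1
expression but *not* the GLUTratio if the ratio is reading immune
infiltration rather than oxygen tension.

## Module scores and copy-number calling

Single-cell and spatial stages score gene programs with a binned-control
**module score**: genes are placed into `nbin = 24` equal-occupancy bins
of average expression; for each program gene, up to `nctrl = 100` control
genes are drawn (without replacement, capped at the bin size) from its
bin; the score of a cell is the mean expression of the program genes
minus the mean of the pooled control genes. Matching controls on
abundance removes the depth/abundance component that a raw mean would
keep. Two consequences worth knowing: when the program is the whole gene
universe the pooled controls *are* the universe and the score is exactly
zero; and when the universe is small the bin count falls back to
`max(2, n_genes/3)` so every bin keeps a few genes. The control draw is
seeded and reproducible.

Malignant cells in tumors without a usable epithelial marker are called
from chromosome-level dosage: the **CNA score** is simply the module
score of all genes annotated to a chromosome (chromosome 7 by default,
the canonical gain in glioblastoma). Cells from a clone carrying the gain
score high; cluster-median CNA scores are split by a deterministic
one-dimensional two-means (all split points of the sorted medians are
scanned for minimal within-group sum of squares) and the high group is
called cancer. This is a coarse proxy, not an inferCNV-style segmental
profile — it detects whole-chromosome dosage shifts, which is all the
downstream cancer/immune dichotomy needs. Composition differences between
cell types leave a small residual bias in null CNA scores (the null AUC
hovers slightly above 0.5 rather than at it), which is why the null
acceptance band is 0.5 ± 0.1 rather than a point.

## The single-cell chain

The clustering pipeline follows the standard single-cell recipe, each
step with its conventional defaults: per-cell log-normalization
($\ln(1 + 10^4 \cdot x / \mathrm{total})$); 2000 highly variable genes by
the variance-stabilizing criterion (loess fit of $\log_{10}$ variance on
$\log_{10}$ mean, span 0.3; genes ranked by the variance of standardized
values clipped at $\sqrt{n}$); per-gene z-scaling clipped at $\pm 10$;
PCA to 10 components with signs fixed by the largest-magnitude loading;
a $k = 20$ shared-nearest-neighbor graph (neighbor sets include the cell
itself; edge weight is the Jaccard overlap of neighbor sets, pruned below
1/15); and Louvain modularity clustering at a dataset-dependent
resolution (0.2–1.0 in the published analyses; 0.5 is used for the
four-type synthetic data). Cluster labels are re-indexed by decreasing
size, and the whole chain is a pure function of the input and the seed.

Markers are detected per cluster with one-vs-rest Mann–Whitney U tests;
the fold change is $\ln$ of the ratio of $(\mathrm{mean}\,
\mathrm{expm1} + 1)$ between groups (the convention of the dominant
single-cell toolchain), BH adjustment is applied within each cluster's
gene family, and pairwise contrasts gate on both $|\log FC| > 0.25$ and
FDR $< 0.05$. Cell types are annotated from fixed marker rosters (cancer:
EPCAM; T: CD3D/CD8A/CD4; B: CD79A/IGHM; myeloid: CD68/LYZ): a cluster
takes the type with the highest marker-set mean provided that mean also
exceeds the set's across-cluster mean; clusters clearing neither gate
stay `unknown` and are excluded (as class `other`) from cancer-vs-immune
comparisons, since their identity is unresolvable from the rosters. Ties
break by the fixed roster order, for determinism.

## The spatial stage

Single-spot counts of an individual gene are sparse, so each GLUT is
represented by the module score of its top-$k$ ($k = 50$) *positively*
correlated genes across spots (Pearson, anchor excluded from its own
module so the score is not a restatement of the anchor; strictly fewer
genes are used, with a warning, if fewer correlate positively). Spot-wise
Pearson correlations of these module scores against ImmuneScore and
EPCAM expression give the spatial association map. Scores never consult
the spot coordinates — only region-based evaluations on synthetic grids
do — so shuffling coordinates leaves every score unchanged. Spatial
counts are log-normalized like cells; regularized count models
(SCTransform-style) are a known alternative and out of scope here, which
matters only if one wants to match a specific published spot-level value
rather than the planted-truth properties tested here.

## The statistical kernel

The Mann–Whitney U implementation uses exact enumeration of all
$\binom{n_1+n_2}{n_1}$ group assignments of the pooled values whenever
both groups have at most eight observations — this handles ties exactly,
which the usual exact algorithms do not — and a tie-corrected normal
approximation with continuity correction otherwise. The two-sided exact
p is twice the smaller tail, capped at 1 (so identical samples give
exactly 1). The exact branch is verified against a brute-force
pair-counting oracle over all group sizes up to six; the approximation's
type-I error at nominal 0.05 is required to land in [0.03, 0.07] over
10,000 null simulations. Kruskal–Wallis, Pearson tests, BH adjustment and
the hypergeometric upper tail delegate to R's own `kruskal.test`,
`cor.test`, `p.adjust` and `phyper`; over-representation rows gate on raw
p $< 0.05$ and BH-FDR $< 0.2$ within the tested collection, and the
universe must always be supplied explicitly.

## What the synthetic data emulates — and what it does not

The generators exist so that every downstream claim can be tested against
a planted truth.

**Bulk cohorts** mix a cancer and an immune expression profile per sample
with immune fraction $f \sim U(0,1)$: SLC2A1, EPCAM and the
hypoxia/glycolysis sets scale with the cancer compartment by the
`immune_effect` fold (default 8), SLC2A3, the cytolytic genes and the ten
immune signatures with the immune compartment by the same fold, and
counts are drawn from a negative binomial (dispersion 0.3, a typical
bulk-RNA-seq over-dispersion) around the mixed means with lognormal
library-size factors (σ = 0.2). The immune compartment is conceptually a
0.4 T / 0.2 B / 0.4 myeloid mixture: the three cell-type marker rosters
carry their mixture weight, while compartment-wide immune genes carry the
full fold. Tying hypoxia/glycolysis to the cancer profile plants the
decoupling result (hypoxia tracks GLUT1, not GLUTratio) as a recoverable
construction.

**Single-cell data** draw four discrete types (default 40% cancer, 30% T,
15% B, 15% myeloid) with type-specific means: cancer over-expresses
SLC2A1 (`glut_effect`, default 6) and EPCAM (`marker_effect`, default 6);
immune types over-express SLC2A3 and their marker rosters. Each immune
type additionally expresses its cognate signature genes (NK and the
cytotoxic genes ride with T; granulocyte and phagocyte signatures with
myeloid) at the weaker fold $\sqrt{\mathrm{marker\_effect}}$ — real cell
types differ along programs, not just along two marker genes, this keeps
the single-cell profiles consistent with the bulk immune mixture, and the
weaker fold keeps the named markers at the top of every fold-change
ranking. An optional `chr7_gain` multiplies all chromosome-7 genes
(fifty background genes are annotated to chromosome 7, enough for a
stable module score) in cancer cells only. Setting every effect to 1
removes all structure, which is how the calibration tests build their
nulls.

**Spatial grids** place spots on an integer lattice with a rectangular
tumor region: immune fraction ≈ 0.1 (uniform 0.05–0.15) inside and ≈ 0.7
(uniform 0.6–0.8) outside, with the bulk mixture model per spot.

All generators are pure functions of their arguments including the seed,
and the truth record (fractions, labels, amplification flags, expected
library sizes, planted gene programs) covers every emitted observation.

What the simulations deliberately omit: doublets, ambient RNA, batch
effects, continuous differentiation gradients, spatial bleed-over between
adjacent spots, and realistic gene–gene correlation beyond the planted
programs (background genes are independent). Passing the recovery tests
therefore shows that the pipeline correctly inverts its own generative
assumptions — mixtures, discrete types, chromosome-scale dosage — not
that it is robust to every artifact of real tissue data.

## Problem sizes and numerical choices

The validation suite runs the bulk stage at 200 samples × 500 genes, the
single-cell chain at 2000 cells × 400 genes (1000 cells for CNA
calling), spatial grids at 20 × 20 spots, and calibration loops at 40
synthetic seeds for marker detection and 10,000 draws for the rank test —
sizes at which every planted effect is comfortably detectable and the
whole suite stays desk-scale. Other conventions: zero-variance genes are
never selected as variable and z-scale to zero; constant vectors are
rejected by the correlation tests rather than returning NaN; Kruskal–
Wallis on a fully tied pooled sample returns H = 0, p = 1 by convention;
p-values below 10^-300 are clamped before log-reporting; and every
stochastic step (control draws, Louvain, simulations) takes an explicit
integer seed. Two-dimensional visualization is provided as a
force-directed layout of the SNN graph seeded with the leading principal
components; no quantitative result depends on it.
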