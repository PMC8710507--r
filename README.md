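# glutme

Glucose-transporter profiling of the tumor microenvironment (TME) from
bulk, single-cell and spatial transcriptomes.

Cancer cells and tumor-infiltrating immune cells compete for glucose, but
they import it through different transporters: GLUT1 (*SLC2A1*) dominates
in malignant cells, GLUT3 (*SLC2A3*) in immune cells. `glutme` implements
a pipeline built around the **GLUTratio**,

```
GLUTratio = (CPM_SLC2A3 + 1) / (CPM_SLC2A1 + 1)
```

a per-sample surrogate of immune (versus cancer) glucose metabolism, and
relates it to a composite immune enrichment score,

```
ImmuneScore = Σ ssGSEA(signature_c),   c ∈ {B cells, CD4 T, CD8 T, DC,
                                            eosinophils, macrophages,
                                            monocytes, mast cells,
                                            neutrophils, NK cells}
```

computed by single-sample gene-set enrichment (a rank-weighted
running-sum statistic) over ten immune cell-type signatures. Around this
core the package provides:

- **Bulk scoring** — CPM normalization, ssGSEA, ImmuneScore, cytolytic
  score (geometric mean of granzyme/perforin CPM), hypoxia score,
  GLUTratio.
- **A single-cell pipeline** — log-normalization, variance-stabilized
  highly-variable-gene selection, z-scaling, PCA, shared-nearest-neighbor
  graph, Louvain clustering, Mann–Whitney marker detection, marker-based
  cell-type annotation, and chromosome-7 copy-number module scores for
  calling malignant cells when no epithelial marker is available.
- **A spatial stage** — per-spot module scores over each GLUT's top-50
  positively correlated genes, correlated spot-wise with ImmuneScore and
  EPCAM expression.
- **A statistical kernel** — Mann–Whitney U (exact, tie-aware enumeration
  for small groups), Kruskal–Wallis, Pearson correlation tests, BH-FDR,
  and hypergeometric over-representation of gene sets.
- **Synthetic-data generators** — seeded bulk, single-cell and spatial
  simulators with planted ground truth (immune fractions, cell-type
  labels, chromosome-7 gains), so every stage is validated end to end.

It is an analysis toolkit for computational biologists studying tumor
immunometabolism who want the full chain — normalization to spatial
correlation maps — reproducible from a count matrix and a GMT file.

## Worked example

Simulate a 200-sample bulk cohort in which each sample mixes a cancer and
an immune compartment (immune fraction uniform on \[0, 1\], eight-fold
planted effects), then recover the GLUTratio–immune association:

```r
library(glutme)

sim  <- generate_bulk_cohort(200, immune_effect = 8, seed = 1)
cpm  <- cpm_normalize(sim$matrix)
sigs <- builtin_signature_collection()

tab  <- immune_composite_score(cell_type_enrichment(cpm, sigs))
lgr  <- log2(glut_ratio(cpm))

pearson_corr_test(lgr, tab$ImmuneScore)$statistic
#> [1] 0.7253238
cor(lgr, cytolytic_score(cpm))
#> [1] 0.4963525
hx <- hypoxia_score(cpm, sigs$sets$hypoxia)
cor(hx, cpm$values["SLC2A1", ]); cor(hx, lgr)
#> [1] 0.5580609
#> [1] -0.6863558
```

The log2 GLUTratio correlates strongly with the composite immune score
(r = 0.73) and positively with cytolytic activity, while the hypoxia
score tracks GLUT1 expression (r = 0.56) but **not** the GLUTratio
(r = −0.69): the ratio reads immune infiltration, not oxygen tension.

The same chain runs from the shell:

```sh
Rscript exec/glutme simulate bulk --n-samples 200 --seed 1 --out-dir out/
Rscript exec/glutme score --matrix out/bulk.mtx --genes out/bulk.genes.txt \
  --obs out/bulk.obs.txt --out-dir out/
```

which writes `out/scores.tsv` with one row per sample (ten cell-type
enrichment columns, ImmuneScore, GLUTratio, cytolytic and hypoxia
scores). `cluster`, `markers`, `spatial` and `enrich` subcommands cover
the single-cell and spatial stages.

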