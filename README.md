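# brmtls

Analysis of the tumor immune microenvironment of brain metastases (BrM):
marker-based immune deconvolution of bulk RNA-seq, a tertiary lymphoid
structure (TLS) gene signature, rule-based spatial TLS calling from
multiplex-immunofluorescence (mIF) cell maps, and the association and
survival statistics that tie them together. A synthetic-cohort generator
with full ground truth makes every stage testable without access to
patient data.

The package is for computational biologists and biostatisticians working
on the immune landscape of metastatic brain tumors — in particular on
whether organized lymphoid aggregates (TLS: ectopic B/T-cell structures
with dendritic cells, resembling lymph-node architecture) can be read
out from transcriptomes and tissue images, and whether they stratify
survival.

## The methods at its core

**Deconvolution.** The abundance score of cell population *p* in sample
*s* is the mean log2 expression of *p*'s marker genes (MCP-counter-style,
arbitrary units, comparable across samples within a population). The
immune cell infiltration score is ICI(s) = Σ<sub>p immune</sub>
score(s, p), excluding endothelial and fibroblast populations, with
low/intermediate/high groups at the empirical tertiles. Immune classes
IC1..IC6 come from Ward/Euclidean hierarchical clustering of z-scored
scores, relabelled by ascending mean ICI.

**TLS signature.** From a 46-gene candidate compendium (12-chemokine
signature, B-cell, dendritic-cell, melanoma-TLS, TLS-hallmark and Tfh
lists), genes are selected by Pearson correlation with the 12-chemokine
seed score, discarding low-expressed (< 1 TPM mean) and negatively
correlated candidates. The per-sample score is the geometric mean
exp(mean(log(TPM + 1))); classes TLS1 < TLS2 < TLS3 come from Ward
clustering on signature genes, and the survival stratification is a
median split. The cytolytic score is mean(log2(GZMA+1), log2(PRF1+1)).

**Spatial TLS calling.** DBSCAN-style density clustering (eps = 30 µm,
min_pts = 10) of T and B lymphocytes in phenotyped cell maps; an
aggregate is a **TLS** if it is perivascular (centroid ≤ 50 µm from a
vessel), has ≥ 500 member cells and a B-cell predominance
(B/(B+T) > 50%), and an **intermediate TLS** if it additionally contains
Lamp3+ dendritic cells. A sample is TLS-positive iff it carries at least
one such call.

**Statistics.** Mann-Whitney U / Kruskal-Wallis comparisons (two-sided),
Benjamini-Hochberg correction, Pearson correlation, RNA-vs-mIF
concordance, Kaplan-Meier/log-rank, Cox proportional hazards (Breslow
ties) with a plain-text forest table, and binomial logistic enrichment.

## Worked example

```r
library(brmtls)

res <- run_brm_pipeline(sim_config(seed = 2), out_dir = "cohort_out")

head(res$signature, 5)
#> # A tibble: 5 × 4
#>   gene  sources                  r mean_expr
#>   <chr> <chr>                <dbl>     <dbl>
#> 1 FCER2 b_cell               0.982    13626.
#> 2 CCL5  chemokine12          0.980     6998.
#> 3 SELL  hallmark             0.979     2603.
#> 4 CR1   b_cell               0.979    13446.
#> 5 CCL21 chemokine12,hallmark 0.977     4611.

res$km
#> Kaplan-Meier / log-rank: chisq = 18.499 on 1 df, p = 1.7e-05 (n = 60, events = 46)
#> # A tibble: 2 × 2
#>   group median
#>   <chr>  <dbl>
#> 1 low     17.8
#> 2 high    64.2

res$cox
#> term                           HR             95% CI          p
#> ---------------------------------------------------------------
#> tls_levelhigh               0.231 [  0.115,   0.464]   3.97e-05
#> age                         0.990 [  0.960,   1.022]      0.539
#> sexmale                     1.668 [  0.875,   3.178]       0.12
#> extracerebralTRUE           0.803 [  0.428,   1.508]      0.495
#> treatmentpretreated         1.380 [  0.757,   2.513]      0.293
#> n = 60, events = 46

res$concordance
#> RNA vs mIF TLS concordance: 1.000 (n = 12)
```

Reading the output: the 46 candidate genes are ranked by their
correlation with the 12-chemokine seed score (here all planted TLS genes
correlate strongly, r ≈ 0.98, because the synthetic cohort elevates them
8-fold in TLS-positive samples). The Kaplan-Meier comparison of the
median-split TLS-high vs -low groups shows the planted survival benefit
(median 64 vs 18 months; the generator's true log hazard ratio is −0.8,
and the Cox interval [0.12, 0.46] covers the true hazard ratio
exp(−0.8) = 0.45). On this seed the
12 samples with simulated tissue maps are classified identically by the
RNA signature (TLS3 vs rest) and by the spatial rules. Mean ICI by site
on the same cohort keeps the planted ordering, lung (79.8) above breast
(75.1), and the cytolytic score rises across TLS classes (10.7, 11.4,
12.6 for TLS1/2/3).

`run_brm_pipeline()` also writes every artifact as delimited text
(expression and TPM matrices, population and ICI scores, immune classes,
signature, TLS scores, cell maps, vessels, aggregate calls, per-sample
spatial status, clinical table, Cox forest table, ground truth JSON). A
thin command-line wrapper with `simulate`, `spatial` and `survival`
subcommands lives in `inst/cli/brmtls.R`.

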