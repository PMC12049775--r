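---
title: "Methods: immune deconvolution and TLS analysis for brain metastases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune deconvolution and TLS analysis for brain metastases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

brmtls analyses the tumor immune microenvironment of brain metastases
(BrM) along three connected axes: marker-based deconvolution of bulk
RNA-seq, a tertiary lymphoid structure (TLS) gene signature, and
rule-based TLS calling on phenotyped multiplex-immunofluorescence (mIF)
cell maps, tied together by association and survival statistics. This
vignette explains each model, its assumptions, the tunable parameters,
and the design choices that were genuinely open.

```{r setup, eval = FALSE}
library(brmtls)
```

## Expression normalization

Counts are normalized as RPKM, `count / (exon_length_kb ×
total_reads_millions)`, with the per-sample total taken as the column sum
of the count matrix, or as TPM, where per-kb rates are rescaled so each
sample sums to 10^6. TPM is the default input unit for all signature
scores because it is comparable across samples with different length
compositions. Log transforms use `log2(x + 1)`; the pseudocount of 1 is a
convention, exposed as an argument. Per-gene z-scores divide by the
population SD (n, not n − 1) so that a fixed, reproducible convention is
used everywhere; the sample SD is available via `population_sd = FALSE`.
Constant gene rows z-score to all zeros with a warning rather than NaN,
since downstream clustering treats "no information" as "no contribution".

## Marker-based deconvolution

The abundance estimator is the MCP-counter idea reduced to its core: the
score of population *p* in sample *s* is the arithmetic mean of *s*'s
log2 expression over *p*'s marker genes. Scores are in arbitrary units
and are only comparable across samples *within* a population. The default
catalogue ships six immune populations (T cells, B lineage, NK cells,
monocytic lineage, myeloid dendritic cells, neutrophils) and two stromal
ones (endothelial cells, fibroblasts) with small canonical marker lists
(e.g. CD3D/CD3E/CD2/TRAC for T cells). The estimator, not the catalogue,
is the contract: any table of `population, gene, compartment` can replace
it, and the published MCP-counter catalogue is deliberately not
reproduced here.

The immune cell infiltration (ICI) score is the sum of the *immune*
population scores; endothelial cells and fibroblasts are excluded.
Samples are assigned to low/intermediate/high infiltration groups at the
1/3 and 2/3 empirical quantiles (linear-interpolation definition, R type
7), with values tied to a boundary going to the lower group. Some tie
convention had to be fixed; this one is documented and oracle-tested.

Immune classes IC1..ICk are agglomerative clusters (Euclidean distance,
Ward linkage, tree cut at k = 6) of the per-population z-scored score
matrix, relabelled by ascending mean ICI so that IC1 is always the least
infiltrated class regardless of `hclust`'s arbitrary cluster numbering.
Ward versus complete linkage was a genuinely open choice — descriptions
of this kind of analysis are inconsistent about it — so Ward
(`"ward.D2"`) is the default and complete linkage is one argument away.

## The TLS signature

The candidate pool is the union (46 unique genes) of six published
lists: the 12-chemokine TLS signature, B cell markers, activated
dendritic cell markers, a melanoma-derived TLS signature, TLS hallmark
genes, and a Tfh signature. Construction reproduces the published
procedure rather than its published outcome: the geometric-mean score of
the 12-chemokine list is the seed, every candidate is Pearson-correlated
with that seed across samples, and genes with low mean expression
(default floor 1 TPM) or negative correlation (default `min_r = 0`) are
discarded. No stopping rule that would force a particular signature size
is invented: the original 32-of-46 outcome depends on the cohort it was
derived from and is not enforceable on other data. A preset signature can
be loaded from TSV instead.

The metagene score is the geometric mean under a +1 offset,
`exp(mean(log(x + 1)))`, reported without back-subtraction. "Geometric
mean" alone is undefined at zero; the +1 convention is the documented
choice and every worked example follows it (e.g. values 0 and 3 score
2.0). TLS1/TLS2/TLS3 classes come from Ward clustering of samples on
z-scored signature genes, relabelled by ascending mean score — not from
score tertiles — while the separate high/low stratification is a median
split (strictly above the interpolated median is high; the sample at the
median goes low). The cytolytic score is `mean(log2(GZMA+1),
log2(PRF1+1))`; a "log-average" needs a base and zero-handling rule, so
this is fixed and the geometric-mean-of-raw-TPM variant is available via
`method = "geom"`.

## Spatial TLS calling

mIF imaging is upstream of this package: input is a phenotyped cell table
(µm coordinates, phenotypes T/B/DC/macrophage/tumor/endothelial/other)
plus vessel points. Aggregate detection uses DBSCAN semantics on the T
and B lymphocytes only: a core point has ≥ `min_pts` lymphocytes within
`eps_um` (itself included), clusters are connected core neighbourhoods
plus border points. Defaults `eps_um = 30`, `min_pts = 10` correspond to
"about ten lymphocytes within a 30 µm radius", a density that separates
organized aggregates from diffuse infiltration at typical lymphocyte
packing; both are exposed, as no detector or parameters are canonical for
this dichotomy. Lamp3+ dendritic cells and macrophages are not part of
the clustered point set; they are counted as belonging to an aggregate
when within `eps_um` of any member lymphocyte, because the maturity rule
below only requires their presence inside the structure.

Classification applies the rules: a perivascular aggregate with at least
500 member cells and a predominance of B cells (B fraction strictly
above 50%) is a TLS; with at least one Lamp3+ dendritic cell present it
is the more mature "intermediate TLS". The B fraction is computed over
lymphocytes, B/(B+T), reading "predominance of B cells" against the
lymphoid aggregate; the all-members denominator is available via
`b_frac_denominator`. Whether the 500-cell floor counts lymphocytes only
is ambiguous in prose descriptions; here it counts cluster members
(lymphocytes), which is also the configurable default. "Perivascular"
has no standard quantitative definition; the default is centroid within
50 µm of the nearest vessel point, logged in every report and
configurable. A sample is TLS-positive iff it has at least one TLS or
intermediate-TLS call; its TLS score is the count of such calls.
"Diffuse infiltration" is operationalized as the absence of any detected
cluster — a pragmatic reading, not an asserted definition.

## Statistics

Group comparisons dispatch the two-sided Mann-Whitney U test (two
groups) or Kruskal-Wallis (three or more); `wilcox.test()`'s default
exact-vs-normal switch applies and is documented in the help. Multiple
testing uses Benjamini-Hochberg. RNA-vs-tissue concordance collapses
TLS1/2/3 to binary with TLS3 → positive by default (TLS2+TLS3 is the
exposed alternative); how three RNA classes should map onto a binary
tissue status is underdetermined, so the mapping is a parameter rather
than a claim. Survival uses Kaplan-Meier/log-rank and Cox proportional
hazards via the survival package with Breslow tie handling by default
(Efron optional) — Breslow is the variant that is simplest to verify
against an independent hand-written partial-likelihood oracle, which the
test suite does. Categorical covariates enter as treatment-contrast
dummies. The logistic enrichment of a binary outcome in a binary
predictor equals the 2×2 log odds ratio; zero cells fall back to a
Haldane-corrected estimate with a warning.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
not real transcriptomes. Defaults define a 60-sample cohort over five
primary sites — lung (20), melanoma (12), breast (14), kidney (7), colon
(7) — with latent immune infiltration ordered lung > melanoma > kidney >
colon > breast and site-specific TLS-positive fractions (lung 0.50, melanoma 0.35,
kidney 0.25, colon 0.15, breast 0.10), echoing the clinical
observation that lung-derived BrM are the most immune-rich and
breast-derived the least. Counts are Poisson around a log-linear model:
per-gene lognormal baselines (log-mean log 50, log-SD 1), marker genes
loading on their population's latent level (truncated normal around the
site mean, SD 0.3), an 8-fold elevation of all TLS-related genes in
TLS-positive samples, lognormal library factors (SD 0.3) and lognormal
gene-by-sample jitter (SD 0.1). GZMA and PRF1 are coupled to TLS status
so the cytolytic-score contrast is part of the planted truth. Three decoy
families with known behaviour are always planted for
signature-construction tests: co-varying genes outside the published
lists (LTB, POU2AF1, FDCSP, TNFRSF13B, CD38), anti-correlated
brain/tumor genes (SOX2, OLIG2, GFAP, depressed by the TLS fold), and
near-silent genes (CDX2, ALB, ~10^-6 expected counts — far enough below
the 1 TPM floor that a stray Poisson count cannot lift them over it in a
~115-gene universe).

Cell maps are homogeneous Poisson background (200 cells/mm² over a 2×2 mm
region, fixed phenotype frequencies) with uniform vessel points and
planted Gaussian aggregates (SD = radius, default 40 µm) whose phenotype
counts are exact — `round(b_frac × n)` B cells, the rest T, exactly
`n_dc` dendritic cells — rather than Bernoulli draws, so spatial
acceptance checks can be exact. Perivascular centres sit within 20 µm of
a vessel; distant centres are rejection-sampled at least 250 µm from all
vessels, making the perivascular rule unambiguous at the 50 µm default.
Survival times are exponential with hazard `h0·exp(β·TLS_high)`
(defaults h0 = 0.03/month, β = −0.8), with independent uniform censoring
whose upper bound is solved numerically to hit the requested censoring
fraction.

What the generator does *not* emulate — transcriptome-wide correlation
structure, batch effects, compositional tissue architecture, informative
censoring — bounds what green tests show: they demonstrate that the
implementation recovers planted structure under its own model, not that
the biology of any particular cohort will behave this way.

## Numerical choices and problem sizes

Determinism: one seed in `sim_config()` fixes the bulk cohort; the
pipeline derives spatial and survival seeds from it by fixed offsets.
Cluster relabelling (by mean ICI or mean TLS score) makes hierarchical
clustering output deterministic given the data. Degenerate inputs have
defined behaviour: constant rows z-score to zero with a warning,
constant candidate genes are dropped from signature construction,
all-equal scores median-split to all-low with a warning, maps without
vessels are never perivascular (with a warning), and zero-event survival
data raise an informative error.

The verification suite uses problem sizes chosen to make the checks
sharp but quick: formula oracles at 10^-10 on dozens of random matrices;
signature recovery on the 60-sample default cohort; median-split
recovery averaged over 20 seeds at fold 8 on a balanced-prevalence
variant (`tls_frac = 0.5`) — a median split labels half the cohort high
by construction, so its agreement with planted status is bounded by
`1 − |prevalence − 0.5|` and is only a meaningful recovery measure near
balanced prevalence; spatial recovery on 20 seeded map cohorts with
planted configurations at least 20% away from every rule threshold;
log-rank type-I error over 500 replicates at n = 200; and Cox recovery
of β = −0.7 at n = 500.

## Known limitations

The marker catalogue is intentionally minimal and should be replaced for
serious use on real data. The signature's size is data-dependent by
design. DBSCAN's border-point assignment is order-dependent in the rare
case of a border point adjacent to two clusters; on organized tissue
this does not arise, but it is why exactness tests compare against a
connected-components oracle rather than fixed labels. The spatial module
starts from phenotyped coordinates and cannot compensate for upstream
segmentation or phenotyping errors. P-values in the enrichment fallback
(Haldane) are Wald approximations.
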