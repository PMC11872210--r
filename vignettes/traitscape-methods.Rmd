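---
title: "Methods: trait-scape plasticity indices and SSR genotype diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait-scape plasticity indices and SSR genotype diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitscape)
```

`traitscape` analyses two linked datasets on clonal *Spartina*
cord-grasses: a microsatellite (SSR) survey of 79 field samples, and a
full-factorial greenhouse experiment crossing six clonal donor
individuals (three hybrid, three allopolyploid) with two water levels
(well-watered vs. drought) and two CO₂ levels (ambient vs. elevated),
six pots per cell. This vignette explains the models and procedures, the
parameters that matter, what the synthetic generator does and does not
emulate, and the numerical choices made where the design was open.

## 1. The trait-scape and the plasticity indices

### Model

Six functional traits are measured per pot: stomatal length (μm),
root-to-shoot ratio (dimensionless), leaf area (mm²), stem height (cm),
stem diameter (mm) and stem density (stems per pot). After imputation
(below), the replicate × trait matrix is ordinated by PCA. Because the
traits mix units spanning four orders of magnitude, columns are centered
and scaled to unit variance (correlation-matrix PCA); `scale = FALSE` is
available but not recommended. All k = 6 components are retained.

Retaining all components makes the ordination an isometry: the Euclidean
distance between two replicates in full score space equals their
distance in centered/scaled trait space (tested to 1e-9). That is the
property that makes the plasticity indices well-defined — they measure
trait-space displacement, not an artefact of a truncated projection. The
two-dimensional trait-scape plot is only a visualization.

The **multivariate plasticity index** of a group (individual or
cytotype) under a treatment contrast is the mean distance over all n·m
pairs of (ambient replicate, treatment replicate); within-environment
pairs never enter. The ambient reference cell is well-watered × ambient
CO₂ throughout. The **trait-variation index** of an individual is the
mean distance of its ambient replicates to the centroid of *all* ambient
replicates — a measure of standing trait variation in the common
environment.

Two aggregations of MVPi to the cytotype level are defensible (pool all
replicate pairs of a cytotype, or average the per-individual indices);
since the source analysis does not fix one, `plasticity_by_contrast()`
reports both (`mvpi_pooled`, `mvpi_mean_individual`). They agree closely
on balanced data and both are tested.

Useful structural facts, all property-tested: MVPi is invariant under
rotation and translation of score space; it is bounded below by the
distance between the two environment centroids (Jensen); with one
replicate per environment it reduces to a single Euclidean distance.

### Imputation

Missing trait values (a leaf lost, a stomatal preparation failed) are
completed by regularized iterative PCA: mean-initialize, then iterate
(center/scale → SVD → reconstruct at rank S with singular values shrunk
by the estimated noise variance, the mean of the discarded eigenvalues →
re-fill the missing cells) until the imputed entries change by less than
`tol` in Frobenius norm. Defaults: `n_components = 2` (the number of
interpretable trait-scape dimensions), `tol = 1e-8`, `max_iter = 1000`;
non-convergence warns and returns the last iterate. Observed entries are
never modified. On data of exact rank S the procedure recovers masked
entries exactly (tested to 1e-6), and on noisy low-rank data it beats
column-mean imputation in masked-cell RMSE (tested). The number of
components used inside imputation is exposed because no value is fixed
by the source analysis; 2 is the default for the same reason the
trait-scape is interpreted in two dimensions.

## 2. Statistics

### Factorial ANOVA

Pot-level responses are first averaged to one mean per individual ×
treatment combination among surviving pots — the individual replicate,
not the pot, is the unit of replication — giving 24 units in the full
design. The fixed-effects model is

`response ~ cytotype * (water * co2)`

with sequential (type I) sums of squares in exactly that term order,
matching the default behaviour of `aov()`. The experiment is
near-balanced, so the choice of SS type is minor, but it is documented
and the balanced-design order-invariance is tested. Responses are
Box-Cox transformed by default.

The Box-Cox exponent λ is chosen per response by profile-likelihood
maximization on the grid [−2, 2] step 0.01 with one quadratic refinement
around the grid maximum; |λ| < 1e-6 uses the log limit. λ is estimated
per response variable, not globally. The estimate is cross-checked
against `MASS::boxcox()` in the test suite.

Assumption checks report Shapiro–Wilk on residuals and Levene's test
with median centering (the Brown–Forsythe variant — the robust default,
chosen because the source analysis names the test but not the centering).
Post hoc comparisons use Tukey HSD; at two groups the Tukey p-value
equals the pooled two-sample t-test (q = √2·|t|), which is tested, as is
its conservativeness relative to unadjusted pairwise t-tests for k > 2.
Under a true null the factorial ANOVA's type-I error at α = 0.05 stays
within [0.035, 0.065] across 2,000 simulations (tested). Indices (MVPi,
trait variation) are compared with one-way ANOVA + Tukey HSD: df = 5
across six individuals, df = 1 across two cytotypes.

### Leaf-area allometry

Leaf area is predicted from caliper measurements via
`area = intercept + slope · width · length`, fitted by OLS on the single
regressor width × length. The published fit (intercept 86, slope
0.63224) is available as `leaf_area_model(86, 0.63224)`. Units are
carried as given and never converted: the published coefficients fix the
scale, and their area unit is treated as instrument-native. No power-law
alternatives and no per-cytotype fits are offered (the source fit pooled
10 + 10 leaves).

## 3. SSR genotype analysis

Alleles are PCR fragment sizes (bp) at eight loci (MS02, MS07,
MS13–MS18). Because allele dosage is unobservable in a dodecaploid,
alleles are treated as dominant presence/absence markers. Choices:

- **Binning** (`bin_alleles`): single-linkage chains of sizes with gaps
  ≤ `bin_width` (default 1 bp) collapse to the bin's modal size; the
  source binning was visual, so the width is exposed. Known artefact
  alleles (two in MS15/MS17) are removed via an exclusion list.
- **Genotype calling**: identical allele sets at every locus share a
  label; labels run A, B, C… by descending count, ties broken
  lexicographically on the serialized allele string so labels are
  sample-order invariant. Frequencies are count/stratum × 100, rounded
  half-up to one decimal to match the published table format.
- **Dissimilarity**: per-locus symmetric-difference counts summed over
  loci. A locus with failed amplification (empty set) in either sample
  contributes 0 rather than a maximal difference, so amplification
  failure does not inflate divergence. Whether the original distance
  counted per-allele or per-class differences is not stated; per-allele
  symmetric difference is used, and it is a metric on the binary
  encoding (property-tested).
- **Minimum spanning network**: a Kruskal MST plus every non-tree edge
  whose weight ties the maximum-weight edge on the tree path between its
  endpoints — all equally-minimal alternatives are kept. MST minimality
  is verified against exhaustive spanning-tree enumeration (≤ 6 nodes,
  via Prüfer sequences) and against igraph's independent implementation.

The survey reports "an overall 16 alleles" while the per-marker table
lists more distinct fragment sizes; the count evidently refers to the
modal genotype's allele complement. The package therefore reports both
`n_alleles` (distinct alleles in the population) and `n_modal_alleles`
(genotype A's complement, 16 on the reconstructed population) and
hard-codes neither.

`ewst_population()` reconstructs a 79-sample population from the
published per-marker carrier counts. Per-locus class counts are exact;
the multilocus combinations are synthetic, because the published table
is marginal per locus — so per-marker frequencies reproduce exactly,
while multilocus genotype counts do not.

## 4. The synthetic generator

`generate_greenhouse()` emulates the study design: 6 individuals × 2 ×
2 × 6 = 144 pots, 21 dead/senescent + 9 removed (n = 114 analysed).
Trait values are drawn per (cytotype, water, CO₂) cell from a normal
truncated at zero (positive-valued traits; truncation mass is negligible
at the calibrated means); stem density is rounded to a non-negative
integer. One integer seed drives everything; equal seeds give
byte-identical CSVs (tested).

Calibration of `spartina_trait_model()`: stomatal length 27.5 ± 2.1 μm
(hybrid) and 38.2 ± 3.0 μm (allopolyploid), treatment-independent;
well-watered biomass 13.8 ± 6.3 g (hybrid) and 9.5 ± 4.4 g
(allopolyploid), with drought cell means split by CO₂ level so the
pooled drought decrease (−57 % / −47 %) and the control-vs-full-treatment
decrease (−52 % / −36 %) both hold. The remaining traits have no
published means; field-realistic values were chosen once with the
reported qualitative structure (hybrid root:shoot peaks under
well-watered × elevated CO₂ and drops under drought × elevated CO₂;
the allopolyploid's size traits respond to CO₂, the hybrid's do not) and
are not tuned thereafter. Missingness is injected completely at random
among survivors (the original missingness pattern is unreported);
defaults: 5 % for stomatal length, 2 % for other ordination traits, 0
for biomass.

Deliberate simplifications — and therefore what passing tests do *not*
show about real data: mortality is treatment-independent and uniform
(only totals are reported); individuals within a cytotype share cell
means, so between-individual variance is purely sampling noise; traits
are drawn independently within a cell, so the generator has no
trait-trait correlation structure beyond what treatment contrasts
induce. Consequently the generator reproduces design arithmetic, index
behaviour and test calibration, but not the exact published ordination
percentages or F statistics, which depend on the deposited raw data.

`generate_ssr()` emulates a clonal population: a fixed
`round(dominant_fraction · n)` samples carry the modal 16-allele
complement; each remaining sample (with probability `rare_allele_rate`)
gains 1–4 rare alleles from per-locus pools or loses 1–3 modal alleles,
mirroring the reported variant structure.

## 5. Problem sizes and reproducibility

The test suite builds all fixtures in code. Simulation sizes were chosen
as the smallest that make each check statistically meaningful: 2,000
null datasets for the type-I-error calibration (binomial SE ≈ 0.005 at
p = 0.05), 100 seeds for the generator-calibration and
direction-recovery checks, 1,000 random instances for the isometry
property, 100 instances of exhaustive spanning-tree enumeration at ≤ 6
nodes. `scripts/acceptance.R` recomputes the headline quantities from
scratch at n = 10,000 (stomatal calibration) and n = 20 (allometry
refit), seeded from its `--seed` argument.

## 6. Known limitations

- The trait model is normal (truncated at zero); real trait
  distributions may be skewed, which is why the inference path
  Box-Cox-transforms responses.
- MVPi inherits the scaling choice of the ordination: with
  `scale = FALSE` high-variance traits dominate the index.
- The MSN tie-retention keeps ties on the *tree path maximum* criterion;
  with many equal weights (typical for small allele-difference counts)
  the network can be dense — that is intended, as ties are real
  ambiguity in clonal descent.
- `frequency_table()` denominators are stratum sizes including samples
  with failed amplification at that locus, matching the published
  table's fixed n = 7/72/79 denominators.
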