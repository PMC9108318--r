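---
title: "Community assembly analysis of presence/absence eDNA data under seasonal hypoxia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community assembly analysis of presence/absence eDNA data under seasonal hypoxia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

In stratified coastal bays, summer warming isolates the bottom water and its
dissolved oxygen (DO) can collapse below the conventional hypoxia threshold
of 2 mg/L.  Two metacommunity hypotheses make opposite predictions about
what this does to fish species composition across the two water layers:

* **Species sorting**: the severe bottom environment filters species by
  their tolerance traits, so surface and bottom communities should *diverge*
  when the DO gradient is steepest.
* **Neutral avoidance / mass effect**: the severity harms or repels fish
  *irrespective of identity*; individuals move surface-ward, compositions
  mix, and the layers should *converge* despite the larger environmental
  heterogeneity.

`hypoxbeta` implements the complete analysis chain needed to separate these
hypotheses from monthly presence/absence eDNA metabarcoding surveys of a
bay sampled at two layers, together with a synthetic metacommunity
generator that produces data under either regime so every stage can be
validated without field data.

# The data model

The pipeline ingests three tables: long-format detections
(`sample_id, species_name, detected/count`; read counts are collapsed to
presence/absence because eDNA read counts correlate unreliably with
abundance), sample metadata (`site_id, month, layer, depth`), and
per-sample environment (`dissolved_oxygen, temperature, salinity`).
Detections are filtered against two curated lists — names unmatched in the
reference fish database, and species whose known habitat excludes the study
area — with the name filter taking precedence when a species appears in
both.  The retained detections become a binary samples-by-species
community matrix; species never detected in a retained sample are dropped,
so richness counts retained species only.

# Season classification

A month is *hypoxic* when the minimum DO over all its samples (both layers)
is strictly below the threshold (default 2 mg/L, the conventional value in
the hypoxia literature; the comparison is strict because the definition is
"falls below").  All samples of a hypoxic month share the label, so that
samples from one campaign are analysed as a unit.

# Ordination and distance partitioning

Compositional dissimilarity is the Jaccard index on presence sets,
`d = 1 - |A∩B| / |A∪B|`; environmental distance is Euclidean after
per-variable standardization (the three variables have incommensurable
units; the same reasoning makes correlation-matrix PCA the default, exposed
as a `standardize` flag since either convention is defensible).  PCA
components carry a deterministic sign convention (largest-magnitude loading
positive) so plots are reproducible.

NMDS minimizes Kruskal stress-1 with monotone regression under the
primary (weak) tie treatment; stress then depends only on the rank order of
the dissimilarities, which we verify by invariance under monotone
transforms.  The first start is the classical-scaling configuration;
remaining restarts (default 20) jitter it with Gaussian noise of one tenth
of the configuration's spread, and the lowest-stress solution is returned.
Convergence is declared when the relative stress change falls below `tol`
(default 1e-6).  Three dimensions are the default for this data type, and
layer separation per season is summarized by the Euclidean distance between
surface and bottom centroids in the ordination space.

`permanova()` is implemented from the distance-partitioning definition:
with `A = -D²/2` Gower-centred to `G`, the sequential (Type I) sum of
squares of each term is the trace of the corresponding projection-increment
applied to `G`, pseudo-F uses the full-model residual, and p-values come
from free permutation of sample labels (999 by default, seed mandatory).
Sequential SS in the stated term order matches the convention of the
analysis software family this area of ecology uses, and the univariate
Euclidean case collapses exactly to classical ANOVA — one of the package's
cross-checks, along with agreement with an independent implementation on
multivariate data.  Continuous covariates (site depth) are centred before
interactions are built so main-effect and interaction columns are not
needlessly collinear.  Months with fewer than three samples are excluded
from all distance-based stages and the null model (configurable), since
two-sample months contribute one pair and no within-month contrast.

# The fixed-fixed null model

Raw dissimilarity comparisons between seasons are confounded by seasonal
differences in alpha diversity (per-sample richness) and gamma diversity
(the monthly species pool): lower alpha and higher gamma inflate Jaccard
dissimilarity by sampling effect alone.  The null model removes exactly
these two quantities.  For each month separately (one regional pool per
campaign), a sequential trial-swap chain randomizes the month's submatrix
while preserving every row sum and every column sum: each trial picks two
random rows and columns and flips the 2×2 submatrix when it is a
checkerboard.  Defaults: burn-in of `10 × fill` trial swaps and `1 × fill`
between the 999 consecutive draws, where `fill` is the number of
occurrences in the month's matrix.  We verified on structured test matrices
that a ten-fold longer thinning interval leaves the quantile distribution
unchanged, so the chain mixes adequately at these settings.

For every unordered same-month sample pair the observed Jaccard value is
placed in its null distribution by the mid-rank quantile
`q = (#{null < obs} + 0.5·#{null = obs}) / n_null`.  Jaccard values on
small binary matrices are heavily tied, so the observed value is computed
with bit-identical arithmetic to the null kernel — otherwise floating-point
noise silently converts exact ties into 0/1 quantiles.  A pair is flagged
`within_bounds` when the observed value lies inside the 10–90% band of its
null values.  Pairs sharing a sample are not independent; the analysis
deliberately retains this structure (the comparison it feeds mirrors the
reporting convention of the field), and the caveat applies to any p-value
downstream.  The hypoxia/normoxia comparison of quantiles is a two-sided
Wilcoxon rank-sum test: exact enumeration when both groups have at most 12
untied values, tie-corrected normal approximation otherwise.

# Hierarchical occurrence and richness models

Richness is modelled as Poisson (log link) on season, layer, and their
interaction with a site random intercept (season dummy: hypoxia = 1 against
a normoxia reference, matching how that model's coefficients are usually
reported).  Species occurrence uses the hierarchical logistic model

```
logit(p_is) = b0_i + b1_i·Season_s + b2_i·Layer_s + b3_i·Season_s·Layer_s
```

with the fixed dummy coding hypoxia = 0 / normoxia = 1 and surface = 0 /
bottom = 1, every species-level coefficient being a fixed effect plus an
independent normal deviation (diagonal covariance: the model description
this follows states normal coefficient distributions without correlations;
a correlated variant is a one-line formula change).  Fitting is by
Laplace-approximated marginal likelihood (`glmmTMB`), with two-sided Wald
p-values from the normal reference.  To keep per-species information
adequate, the occurrence model is fit to the top 10% most frequently
detected species (ceiling of the fraction; ties broken alphabetically for
determinism).  Whether species respond *individually* to bottom hypoxia is
judged by a likelihood-ratio test between the full model and one whose
interaction is purely fixed: chi-square with df = 1 (one variance
parameter).  Testing a variance on its boundary makes this test
conservative; no boundary correction is applied, matching the convention
of the reporting style this mirrors.

# The synthetic metacommunity generator

The generator's defaults emulate the study design the package targets:
14 sites (depths 6–70 m), 12 monthly campaigns, two layers (≈336 samples),
a pool of 170 species, bottom DO collapsing to ≈1.3 mg/L in June–September
while other months sit near 6 mg/L, and detection thinning of 0.9 per
occurrence.  Temperature follows an annual sinusoid (surface 7–25 °C,
bottom damped and lagged) and salinity freshens slightly at the surface in
summer.  An optional `monthly_n` vector subsamples each month to emulate
failed samples (the published campaign sizes include a two-sample month).

Occupancy follows the hierarchical logistic model above, plus a
species-by-site affinity field `N(0, 3.5²)` representing patchy, localized
distributions — strong horizontal structure, so that monthly communities
carry genuine species-by-sample association beyond what richness and
species totals explain.  A purely additive occupancy model cannot move the
null quantiles at all: sample- and species-level additive effects are
exactly the margins the swap null conditions on, so only species-by-sample
interaction structure is visible to it.  This is why the scenarios differ
in how that structure is expressed:

* `neutral_avoidance` — the species-common surface-ward shift in hypoxia is
  a fixed interaction with near-zero spread (SD 0.05), and mass-effect
  dispersal replaces a fraction (0.5) of each species' occupancy
  probability with its bay-wide mean during hypoxic months.  Mixing at the
  probability scale preserves every species' overall occupancy (so richness
  is driven by the common effects, not by the mixing) while eroding spatial
  structure irrespective of identity.  The conditional interaction mean is
  1.5 logits; the marginal coefficient recovered by the occurrence GLMM is
  smaller (≈0.3–0.6) because unmodelled spatial variance attenuates
  logistic fixed effects, and it is that attenuated magnitude that matches
  what one observes in comparable field analyses.
* `sorting` — species-specific hypoxia responses: interaction coefficients
  `N(0, 1.5²)` (mixed signs), spatial structure expressed equally in both
  seasons.
* `null` — no layer/season structure at all; baseline occupancy and site
  affinity only.

Under `neutral_avoidance` the generator reproduces the qualitative pattern
set of interest: hypoxia-season surface richness rises while bottom
richness falls; the overall null-quantile distribution sits lower in
hypoxia than normoxia (because normoxia expresses spatial sorting that the
null detects, while hypoxic months approach the null's exchangeability);
the occurrence GLMM recovers a positive common interaction with near-zero
random variance.  Under `sorting` the species-specific interaction variance
is materially larger and the season-by-layer PERMANOVA component grows
relative to the `null` scenario.

What the generator does **not** emulate: eDNA transport, degradation, and
vertical mixing (detection is plain Bernoulli thinning), read-count noise,
temporal autocorrelation of occupancy between months, and correlations
among the species-level coefficients.  Passing tests on synthetic data
therefore validate the statistical machinery and the directional logic of
the scenario contrast, not the field-data magnitudes.

# Numerical choices and degenerate inputs

* Pairs of empty samples have an undefined Jaccard value; the default is an
  error, with an explicit `empty_pair = "zero"` opt-in (used inside the
  null model, where margins are fixed and the case can only arise if it was
  present in the observed data).
* Classical scaling can yield fewer than `k` positive eigenvalues; the NMDS
  initial configuration is zero-padded in that case.
* A random-effect variance estimated at zero is reported as a boundary fit,
  not an error; a full model whose log-likelihood falls below its reduced
  model's beyond tolerance triggers an optimizer-failure warning and the
  LRT statistic is clipped at zero.
* All stochastic stages consume sub-seeds derived from the master seed by
  stage-name hashing, so inserting a stage never shifts another stage's
  random stream, and a pipeline re-run with the same configuration is
  byte-identical.

# Problem sizes used in the shipped checks

The package's own validation uses: 1000 random matrices for swap-margin
conservation; a 25-sample × 120-species month (300 pairs, 199 null draws)
for null-quantile calibration; 500 simulations at n = 24 with 99
permutations for PERMANOVA type-I calibration; 100 replicates of 50 species
× 400 samples for occurrence-model recovery; and 20 study-size replicates
(14 sites × 12 months × 2 layers, 199 null draws) for scenario
discrimination.  These sizes were chosen to put Monte-Carlo error well
below the assertion margins while keeping a full validation run in the
minutes range on one core.

# Known limitations

* The Wilcoxon comparison inherits the non-independence of pairs sharing a
  sample; its p-value is anti-conservative to an unquantified degree.
* Sequential SS makes PERMANOVA results depend on term order; the order is
  part of the design specification on purpose.
* The Laplace approximation can bias variance components for very sparse
  species; for the top-frequency species the models are fit to, this is
  negligible relative to sampling noise.
* The LRT on a boundary variance is conservative (no 50:50 mixture
  correction).
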