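# hypoxbeta

Community-assembly analysis of presence/absence eDNA metabarcoding data
from a seasonally hypoxic coastal bay.

## The problem

Monthly eDNA surveys of a stratified bay detect fish species at two water
layers (surface and bottom) across many sites.  In summer, bottom
dissolved oxygen (DO) collapses below the conventional hypoxia threshold
of 2 mg/L.  Does the resulting environmental heterogeneity make surface
and bottom communities *diverge* (species sorting: only hypoxia-tolerant
species persist below) or *converge* (mass-effect avoidance: fish of every
species shift surface-ward, mixing composition across layers)?

`hypoxbeta` is for ecologists who want to answer that question from three
tables — long-format species detections, sample metadata, per-sample
environment — with a reproducible, seeded pipeline:

1. **Season classification** — a month is *hypoxic* when its minimum DO is
   strictly below the threshold.
2. **Ordination** — PCA of the environment; Jaccard dissimilarity
   (`d = 1 − |A∩B|/|A∪B|`) and NMDS (Kruskal stress-1, monotone
   regression, multiple restarts) of composition, with surface–bottom
   centroid distances per season.
3. **PERMANOVA** — sequential distance partitioning with a
   season × layer interaction (and a layer × site-depth model for
   vertical-mixing bias), implemented from the Gower-centring definition
   with free label permutations.
4. **Fixed-fixed null model** — per month, 999 checkerboard-swap
   randomizations preserving every sample's richness and every species'
   occurrence total; each same-month pair's observed Jaccard value is
   placed in its null distribution as a mid-rank quantile
   `q = (#{null < obs} + 0.5·#{null = obs}) / n_null`, and the hypoxia and
   normoxia quantiles are compared by Wilcoxon rank-sum test.  Low
   quantiles mean pairs are more similar than alpha/gamma-diversity
   sampling effects predict.
5. **Hierarchical GLMMs** — Poisson richness (site random intercept) and
   Bernoulli-logit occurrence
   `logit(p_is) = b0_i + b1_i·Season + b2_i·Layer + b3_i·Season·Layer`
   with independent species-level random coefficients, plus a
   likelihood-ratio test asking whether the hypoxia response is
   species-specific.
6. **Synthetic metacommunity generator** — study-size datasets (14 sites ×
   12 months × 2 layers, 170 species, summer bottom-DO trough) under
   `neutral_avoidance`, `sorting`, or `null` assembly scenarios, so the
   whole chain is testable end to end.

## A worked example

```r
library(hypoxbeta)

sim <- simulate_dataset(simulation_config(seed = 7))   # neutral avoidance
cm  <- build_community_matrix(sim$detection, sim$metadata)
lab <- classify_seasons(sim$environment, sim$metadata, threshold = 2)
print(as.data.frame(lab)[6:9, ])
#>   month    min_do  season
#> 6     6 0.5042305 hypoxia
#> 7     7 0.1300186 hypoxia
#> 8     8 0.6004299 hypoxia
#> 9     9 0.3855704 hypoxia

pq  <- pairwise_null_quantiles(cm, lab, null_model_config(n_null = 199, seed = 8))
compare_quantiles_by_season(pq)
#> null-quantile comparison: hypoxia n=1512 (mean 0.502), normoxia n=3024 (mean 0.531)
#> Wilcoxon rank-sum W = 2154577.5, p = 0.001554 (normal approximation)

fit <- fit_occurrence_glmm(cm, lab)   # top 10% most frequent species
fit$fixed[fit$fixed$term == "season:layer", ]
#>          term  estimate        se        z            p
#>  season:layer 0.6996313 0.1344125 5.205107 1.938848e-07
```

The hypoxia-season pairs sit *lower* in their null distributions than the
normoxia pairs (p = 0.0016): after removing richness and species-pool
sampling effects, communities are *more* similar during hypoxia.  The
positive fixed `season:layer` coefficient (bottom occupancy is relatively
higher in normoxia, i.e. depressed during hypoxia) with near-zero
species-specific variance says the surface-ward shift is common to
species, the signature of neutral avoidance rather than species sorting.
`run_pipeline(pipeline_config(...))` executes all stages and
`write_study_report()` emits JSON and markdown reports.

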