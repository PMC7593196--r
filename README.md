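# foramsize

Macroecological analysis of intraspecific shell-size variation in
planktonic foraminifera: population size statistics from individual
shell measurements, a collector-bias audit for museum material,
WGS-84 geodesic matching of sites to environmental and assemblage
data, and AICc multimodel inference on size-environment relationships
— plus a seeded synthetic-data generator so the entire workflow runs,
and is tested, without any external download.

## Who this is for

Micropaleontologists and marine macroecologists working with
individual-level morphometric data (here: shell cross-sectional area
in µm², a proxy for volume) sampled at georeferenced sites, who want
to relate population-level size to sea-surface temperature (SST), net
primary productivity (NPP), and species' relative abundance — and who
need to handle the size bias that hand-picked collections carry.

## The core machinery

**Response variable.** Per population (species x site), shell areas
are natural-log transformed and summarised by mean, median, 75th
percentile, 95th percentile, and maximum. The bias audit
(`bias_audit()`) pairs populations measured in two collections,
computes each metric's residuals from the 1:1 line, and ranks metrics
by mean squared error — identifying the statistic least distorted by
collector behaviour. The 95th percentile (log-P95) is the canonical
winner: robust both to under-collection of small specimens and to the
extreme-value noise of the maximum.

**Covariates.** `nearest_match()` attaches the geodesically nearest
grid record (WGS-84 ellipsoid) per site; `radius_median_abundance()`
returns the per-species median relative abundance over all assemblage
records within 300 km — the maximum modelled postmortem drift of
settling shells.

**Inference.** For each species, ten candidate models of
log-P95 ~ {SST, SST², NPP, SST·NPP, abundance} are fitted by Gaussian
maximum likelihood and ranked by

    AICc = -2 logL + 2k + 2k(k+1)/(n - k - 1),

with k counting all parameters including the residual variance.
Models with ΔAICc < 2 form the equally-plausible set; Akaike weights
and adjusted R² are reported. A species-random-intercept likelihood
ratio test (`lrt_abundance_mixed()`, ML fits via lme4) asks whether
abundance predicts size across species.

## Worked example

```r
library(foramsize)

cfg <- sim_config(n_species = 3, n_sites = 40, individuals_per_site = 20,
                  size_coefficients = c(11.5, 0.05, 0, 5e-4), seed = 11)
ds <- simulate_dataset(cfg)     # specimens + grids + assemblage + truth
report <- run_pipeline(ds)
print(report)
#> Pipeline report: 120 populations, 3 species analyzed
#>   species_01     plausible: sst, sst2, sst+abund, sst+pp
#>   species_02     plausible: sst, sst+pp, sst+abund, sst2
#>   species_03     plausible: abund, sst, sst+pp

report$selection[["species_02"]]$table
#>        label k logLik    aicc delta_aicc   weight  r2_adj
#> 1        sst 3   3.36 -0.0526       0.00 4.04e-01  0.5641
#> 2     sst+pp 4   3.73  1.6733       1.73 1.71e-01  0.5606
#> 3  sst+abund 4   3.64  1.8529       1.91 1.56e-01  0.5587
#> 4       sst2 4   3.63  1.8834       1.94 1.54e-01  0.5583
#> ...
```

The generator's true size model here is a linear SST effect (0.05
log-units per °C) plus a weak NPP effect; the selection table shows
`sst` winning (ΔAICc = 0, weight 0.40, adjusted R² 0.56) with its
close nested relatives inside the ΔAICc < 2 plausible set, and the
covariate-free models ~30 AICc units behind.

The five-stage narrative workflow lives in `analysis/`
(01_simulate → 02_bias_audit → 03_match_covariates →
04_model_selection → 05_sensitivity); each stage is a thin script over
the exported functions and writes its tables under `results/`.

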