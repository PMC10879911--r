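# elevgrad

Analysis of insect species richness and elevational range size along montane
elevational gradients, for community ecologists working with transect survey
data (sweep-net plus hand capture).  The package grew out of work on
Orthoptera assemblages sampled in 100-m elevational bands, but every stage is
generic: any site-stratified occurrence table with mixed survey methods fits.

## What it computes

**Sampling-effort index.**  Hand captures are converted into equivalent
net-survey units so that unevenly surveyed sites become comparable:

    SE = surveys_NET + total_obs_HAND / mean_obs_NET

SE then enters the richness model as a continuous confounding covariate.

**Richness model.**  Site richness (effective-taxon counts, where a genus
record counts only when no congeneric species was recorded at the site or the
curator flagged it as distinct) is modelled by a quasipoisson log-link GLM:

    richness ~ elevation + study_area + SE + vegetation + slope + aspect

with Pearson-estimated dispersion φ, backwards stepwise elimination driven by
analysis-of-deviance F-tests, F = (ΔD/Δdf)/φ̂, and a publication-style
per-term F table.

**Rapoport-effect test (modified Rohde method).**  Per species, the
elevational range is (upper bound of highest occupied band) − (lower bound of
lowest occupied band) and the midpoint is halfway between those extremes;
single-band species get the minimal 100-m range.  Range is regressed on
midpoint with polynomials of order 1–4, compared by AIC (Gaussian likelihood,
σ² counted), adjusted R² and nested F-tests.  Stevens' band-mean and Pagel's
range-extreme estimators are included as comparators.

**Synthetic communities.**  `generate_community()` simulates the whole
design — 28 sites in bands 1100–2500 m across four study areas, elevation-
dependent survey effort, negative-binomial capture counts, genus-rank
records, and a configurable true range–midpoint law (linear Rapoport,
quadratic hump, or constant) — and returns the generating ground truth, so
parameter recovery is testable end to end.

## Worked example

```r
library(elevgrad)

com <- generate_community(scenario_config(), seed = 1)
eff <- effort_from_records(com$occurrences, com$visits)
rt  <- richness_per_site(com$occurrences, com$sites, eff)

spearman_correlation(rt$elevation_band_lower, rt$richness)[c("rho", "p_value")]
#> $rho      [1] -0.489465
#> $p_value  [1] 0.008204067
```

Richness falls with elevation (rho = −0.49).  The stepwise GLM reduces the
eight-term full model:

```r
sw <- backwards_stepwise(rt, c("elevation_band_lower", "study_area",
                               "se_value", "veg_cover", "veg_max_height",
                               "veg_density", "slope", "aspect"))
sw$fit
#> Quasipoisson GLM: richness ~ se_value + veg_max_height + veg_density + slope
#>                estimate std_error
#> (Intercept)      1.0432    0.7298
#> se_value        -0.0909    0.0440
#> veg_max_height   0.0288    0.0105
#> ...
#> dispersion (Pearson) = 0.914
#> null deviance 38.95 (df 27); residual deviance 23.00 (df 23); n = 28
```

(in this seed the vegetation covariates, themselves collinear with
elevation, absorb the elevational trend).  The range–midpoint regression
recovers the hump the default scenario generates (true peak 1850 m):

```r
sp  <- remove_singletons(filter_species_level(com$occurrences))
rng <- species_elevational_range(sp, com$sites)
sel <- select_model(fit_polynomials(rng$midpoint_m, rng$range_m))
sel$best
#> order-2 polynomial: AIC = 332.2, adj R2 = 0.267, RSS = 1034298.1 (n = 24)
#>         b0         b1         b2
#> -3.435e+03  4.522e+00 -1.272e-03
sel$comparisons[1, ]
#>   order_low order_high  f_value df_num df_den     p_value
#> 1         1          2 8.742906      1     21 0.007527603
```

The quadratic beats the linear fit (F(1,21) = 8.74, p = .008) and its vertex
−b1/(2·b2) ≈ 1777 m sits near the generating optimum — a mid-elevation peak,
i.e. no Rapoport effect in this community.

The whole chain, including JSON artifacts and a Markdown report:

```r
run_pipeline(pipeline_config(scenario = scenario_config(), out_dir = "out", seed = 1))
```

or from a shell: `Rscript -e 'elevgrad::elevgrad_cli()' run --out-dir out`.

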