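---
title: "Methods: richness gradients and range-size regression in elevgrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: richness gradients and range-size regression in elevgrad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elevgrad)
```

This vignette documents the statistical machinery in `elevgrad`, its
assumptions, defaults, and the design choices that were genuinely open.

## Bands, effective taxa and the richness table

Sites are stratified into half-open 100-m elevational bands keyed by the
lower bound: a site at 1650 m a.s.l. belongs to band 1600 (`assign_band()`).
The band is the resolution of everything downstream — range sizes are
multiples of 100 m and midpoints multiples of 50 m.

Richness counts *effective taxa*: all species-level taxa, plus each
higher-rank taxon (usually a genus) with no congeneric species recorded in
the same scope, or carrying an explicit curator flag asserting it is clearly
distinct.  The flag exists because "clearly distinct according to where the
identification keys diverge" is a curatorial judgement, not something
derivable from the occurrence table; modelling it as a boolean on the record
preserves the counting rule without inventing taxonomy.  Taxon lists are
pooled across all visits before the rule is applied, per site
(`richness_per_site()`) or per band as the union of its sites
(`richness_per_band()`).

Vegetation structure is aggregated by plain arithmetic means: plot density =
mean of five rod-touch counts, site value = mean over all plots of all
seasons (`aggregate_vegetation()`).  The structural measures are kept as
separate covariates, never combined into a product index, because they can
affect species differently and correlate with elevation individually.
Eye-estimated covers may miss 100% by up to ±5 points before a warning;
renormalisation is available but off — field estimates are reported as
recorded.  Aspect is averaged as raw degrees (as the source covariates were
produced); a circular mean would be more correct but would silently change
the covariate's meaning, so it is not the default.  Rows with missing
covariates are dropped from modelling with a warning, never imputed.

## The sampling-effort index

$$SE = \mathrm{surveys}_{NET} + \frac{\mathrm{total\_obs}_{HAND}}{\mathrm{mean\_obs}_{NET}}$$

SE is an equivalent number of net surveys: the second term asks how many net
surveys would have been needed to catch the hand-caught specimens.  It is
undefined when hand specimens exist but net surveys caught nothing (division
by zero) — `sampling_effort()` raises an error naming the site rather than
returning an arbitrary value.  With no hand captures, SE equals the net
survey count exactly, whatever the net mean.

Survey counts can be inferred from capture records, but then a net survey
that caught nothing is invisible and effort is underestimated.  An optional
visit registry (one row per survey pass) fixes `surveys_NET` exactly; the
synthetic generator always emits one.  Each pass counts as one survey unit,
including repeat same-day passes at windy high-elevation sites.

## Quasipoisson richness model

Richness is a count with variance typically exceeding the mean, so the GLM
uses a Poisson log-link likelihood with a multiplicative dispersion
$\varphi$ estimated from the Pearson chi-square,
$\hat\varphi = \sum r_P^2/(n-p)$ (the standard quasipoisson convention;
deviance-based estimation is not offered).  Point estimates are identical to
the Poisson fit; standard errors scale by $\sqrt{\hat\varphi}$.  Nested
models are compared by analysis-of-deviance F-tests,

$$F = \frac{(D_{reduced} - D_{full})/\Delta df}{\hat\varphi_{full}},$$

referred to $F(\Delta df, df_{res,full})$.  Quasi-likelihood has no true
AIC, hence deviance/F-based selection throughout.

`backwards_stepwise()` repeatedly deletes the term with the largest
non-significant single-deletion p-value.  Two stopping rules are offered
because a strict "delete while any p > α" rule is not what experienced
modellers actually do — marginally informative covariates (e.g. sampling
effort with p ≈ .07) are often retained when deleting them visibly worsens
the deviance.  The default `deviance_guarded` rule therefore only deletes a
term when its deletion F is also below `f_max = 2`, i.e. when removal costs
less than two units of scaled deviance per degree of freedom — the
quasi-analogue of an AIC-improving deletion.  `strict_alpha` gives the
textbook rule.  The elimination trace is recorded and reproducible: the same
table and configuration always yield the same path.

The per-term table (`term_f_table()`) is sequential (type-I) in the model's
stated term order by default, scaled by the final model's $\hat\varphi$,
matching conventional analysis-of-deviance output; single-deletion
(type-II-like) tests are available.  `study_area` enters as an unordered
factor with treatment contrasts, reference level first alphabetically.

Correlation screening uses tie-corrected Spearman rank correlation with the
t-approximation on $n-2$ df.  Screening *reports* collinearity (e.g.
vegetation cover vs slope); exclusion is a configuration choice, because
dropping an ecologically important covariate is a judgement call, not an
algorithm.  Where a share of explained variation is quoted from a rank
correlation it is $\rho^2$, an interpretive quantity, and is labelled as
such.  The richness–elevation correlation is computed on per-site points by
default (28 sites matches the GLM's n); per-band points are available.

## Modified Rohde range–midpoint regression

Only species-rank records are used: members of one genus can differ
ecologically, so genus-level records would blur the species-as-datapoint
logic.  Singletons — species represented by **one individual in the whole
study** (not one site or one visit) — are removed; a single specimen carries
no range information.

For each species, with band width $w = 100$ m:

$$R = (\mathrm{max\_band} + w) - \mathrm{min\_band}, \qquad
  M = \frac{\mathrm{min\_band} + \mathrm{max\_band} + w}{2}.$$

The single-band minimum $R = 100$ m is a consequence of the formula, not a
special case.  The midpoint (rather than the mean elevation of captures)
avoids bias from many observations at one end of a range.  Ranges are
reported as observed — no correction for truncation at the surveyed window
(stored in `attr(, "window")` so boundary-touching species can be flagged).

`fit_polynomials()` fits OLS polynomials of order 1–4 in the midpoint.
Numerically the predictor is centred and scaled; coefficients are
back-transformed to the metre scale by polynomial composition, which is
exact, and AIC/R² are basis-invariant.  AIC uses the full Gaussian
likelihood with $\sigma^2$ counted as a parameter:
$AIC = n\ln(RSS/n) + n\ln 2\pi + n + 2(k+2)$ — identical to `stats::AIC` on
the equivalent `lm`.  `select_model()` takes the AIC minimum; adjusted R² is
reported as corroboration and a disagreement is flagged but AIC wins,
because joint criteria need a deterministic tie-break.  Consecutive orders
are compared by nested F-tests on RSS.  Stevens' band-mean estimator
(points = bands, not independent) and Pagel's range-extreme regression are
comparators only; the phylogenetically corrected cross-species method is out
of scope.

## What the synthetic generator emulates — and what it does not

`generate_community()` reproduces the *statistical structure* the analysis
assumes: 28 sites in bands 1100–2500 m across four study areas (every band
covered); net surveys 3–8 per site increasing with elevation and hand
surveys 2–3 (so effort is confounded with elevation, which is exactly what
the SE covariate exists to absorb); species midpoints uniform over the
window with breadths from a configurable law (quadratic hump by default,
peak 900 m at 1850 m, noise sd 300 m); hard band-interval occupancy so true
ranges are well-defined for recovery tests (a soft-Gaussian option exists
for robustness checks only); log-normal species abundances; and
negative-binomial capture counts whose expectation declines log-linearly
with elevation (default `suit_decay = 4e-3` per m) multiplied by a
log-normal site-quality effect (sd 0.8).  The site effect matters: counts
being overdispersed does not by itself make *richness* overdispersed —
between-site heterogeneity does, and without it the quasipoisson dispersion
of detected richness sits below 1.

Defaults were calibrated once, against the intended scale (≈1600
individuals, ≈40% identified to species, a handful of singleton species, 37
named species in the pool), and then frozen: over 20 seeds the defaults give
≈1570 individuals, ≈630 species-level records, richness–elevation Spearman
rho ≈ −0.7 and dispersion above 1 in most seeds.  About 4 singleton species
arise per seed; pushing the abundance tail to force ≈7 inflated total
abundance unrealistically, so the milder tail stands.

A green test on synthetic data establishes that the pipeline recovers known
structure under the generator's assumptions.  It does **not** establish
robustness to what the generator leaves out: spatial autocorrelation between
nearby sites, phenology and season effects on detectability, observer
drift, taxonomic misidentification, soft range edges, or the shrinking of
available land area with elevation.

Vegetation plots are drawn around the latent site covariates (plot noise sd
5 cm/points).  In the deterministic zero-noise mode, rod-touch counts are
integers constructed to average exactly to the latent density rounded to the
nearest 0.2 (the resolution achievable by a mean of five integers), so
"exact recovery" is exact at that resolution.

## Numerical choices and degenerate inputs

* GLM IRLS runs with deviance tolerance 1e-12 so estimates agree with an
  independent Newton/IRLS oracle to 1e-8; aliased (collinear) designs and
  non-convergence are errors, not silent NA coefficients.
* `anova_f()` of identical models returns F = 0, p = 1 (zero df special
  case); negative F from floating-point noise is clamped to 0.
* Polynomial designs are checked for rank; a constant predictor errors.
* Breadths drawn below 10 m are resampled up to 20 times, then clamped.
* A site whose hand surveys caught specimens while all its net surveys
  caught none would have undefined SE; the generator redraws such sites (up
  to 20 tries) and then drops the hand captures, mimicking a protocol in
  which a site enters the analysis only with usable net data.
* The type-I-error check of the deletion F-test runs at the study's own
  scale (n = 28 sites, Poisson richness, one null covariate); measured
  rejection is ≈0.05 within Monte-Carlo error of 2000 replicates.

## Known limitations

* Stepwise inference is conditional on the selected model; the per-term
  p-values are not corrected for selection.
* The deviance-guarded stopping rule is one defensible reading of
  "minimising the deviance" — published tables produced by hand-guided
  selection cannot be reproduced exactly without knowing each stopping call.
* Observed ranges are truncated at the surveyed window; species touching
  1100 or 2500 m likely extend beyond it, which compresses ranges near the
  boundaries and can itself induce a mid-elevation peak (mid-domain effect).
  The package flags but does not model this.
* DEM processing is out of scope: slope and aspect are consumed as
  precomputed covariates.
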