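---
title: "Methods: specimen-rarefied zonation analysis of abyssal megafauna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: specimen-rarefied zonation analysis of abyssal megafauna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(abyssbio)
```

## The problem

Abyssal plains are sampled by seabed imagery: robots photograph the seafloor
and every megafaunal specimen (> 10 mm) is counted and, where possible,
assigned to a standardized morphotype treated as a species-level unit.
Sampling effort is wildly uneven between surveys, so raw counts cannot be
compared across sites. This package implements a specimen-rarefied design:
occurrences are constrained to geographic locations (10 × 10 km grid cells
within sites) and 200-m depth bins, then resampled without replacement into
equally sized community samples. All inference — alpha diversity, standing
stocks, Bray–Curtis/NMDS beta diversity, gradient regressions and
depth-province statistics — is done on those samples, which makes replicates
exchangeable and minimises spatial autocorrelation within samples.

Two sample sets serve different purposes:

* **BD** (biodiversity): exactly 200 specimens per sample, morphotype-level
  identifications only, frames of any type. Equal specimen counts make Hill
  numbers directly comparable.
* **SS** (standing stock): 450–500 specimens per sample, all identification
  levels, but assembled only from scalable still images whose seabed area is
  known, so density (ind m⁻²) is well defined.

## Survey-design choices

**Projection.** Grid cells are defined in a local equirectangular projection
about the dataset centroid (`x = R cos φ₀ Δλ`, `y = R Δφ`, R = 6371 km).
At 5–20° N the distortion over a 10-km cell is far below the cell size, so a
full geodetic treatment would change nothing while adding a dependency.
Records polewards of |lat| > 85° are rejected rather than mis-projected.

**Binning conventions.** Depth bins and grid cells are half-open and aligned
to multiples of their width (`[4,200, 4,400)` m, cell indices by floor
division). Alignment is a convention, not an inference: it only has to be
fixed and documented so that runs are reproducible.

**Rarefaction policy.** Within each location × bin, specimens are shuffled by
a single seeded generator and partitioned. BD leftovers (`n mod 200`) are
discarded, never pooled across bins or locations — pooling would defeat the
purpose of constraining samples geographically. SS samples accumulate whole
images (an image is never split, otherwise its area contribution would be
ambiguous); when adding an image would push the running count past 500
before 450 is reached, that image is set aside and accumulation continues
with later images, and any residual group that cannot reach 450 is
discarded. The
450–500 window follows the survey-methods convention for stable local
community estimates; it is configurable in `sampling_plan()`.

**Determinism.** Every stochastic step (shuffles, permutations, restarts,
the generator) flows from one explicit integer seed. Two runs with the same
seed produce byte-identical artifacts; this is asserted in the test suite.

## Diversity and uncertainty

Hill numbers of order 0 (richness) and 1 (`exp H'`, Shannon entropy in nats,
exponentiated) are computed per BD sample. `exp H'` ranges from 1 to S and
equals S only for a perfectly even sample, so the S − exp H' gap reads as
dominance concentration.

Province summaries report arithmetic means with two-sided t confidence
intervals (`mean ± t₀.₉₇₅,ₙ₋₁ s/√n`). A bootstrap percentile interval is
available (`province_summary(..., method = "bootstrap")`) but t is the
default: with a handful to a few dozen samples per province the t interval
is the standard convention for error bars and is exactly reproducible.
Provinces with fewer than two samples get `NA` bounds rather than a
fabricated interval.

Accumulation curves are sample-based rarefaction estimated by Monte Carlo:
100 seeded permutations of sample order, cumulative pooled richness at each
step, mean and t-based 95% envelope across permutations. The analytic
expectation (Mao tau, via `vegan::specaccum(method = "exact")`) is used as
an independent cross-check in the tests; the Monte-Carlo route is the
canonical output because it mirrors the stated resampling procedure and
yields an envelope of the same kind at every step.

## Beta diversity

Bray–Curtis dissimilarity is computed on square-root transformed abundances
(down-weighting dominant taxa) via `vegan::vegdist`; the tests verify the
implementation against the literal formula.

NMDS is implemented in the package rather than delegated, because the
algorithmic details matter here and need to be inspectable:

* **Stress.** Kruskal stress-1,
  `sqrt(Σ(d̂ᵢⱼ − d*ᵢⱼ)² / Σ d̂ᵢⱼ²)`, where `d̂` are configuration distances
  and `d*` their isotonic (pool-adjacent-violators) regression on the rank
  order of the input dissimilarities.
* **Ties.** Kruskal's primary approach: within blocks of tied input
  dissimilarities the fitted values may follow the configuration distances
  (implemented by sub-sorting `d̂` inside tied blocks before PAVA), which
  can only lower stress.
* **Optimisation.** Analytic stress gradient with steepest descent and step
  halving (the step also re-grows by 1.5× after successful moves);
  convergence when the stress improvement drops below `1e-6` or after
  `max_iter = 200` iterations. Stress is non-increasing across iterations by
  construction, and the per-iteration trace is returned.
* **Starts.** The first start is classical metric scaling (`cmdscale`), the
  remaining `n_restarts − 1` are seeded Gaussian configurations
  (`seed + 1, …`). A metric start is cheap, deterministic and usually close
  to the global optimum; random restarts protect against its occasional
  failure. The best (lowest-stress) start wins.
* **Output.** The configuration is centred and rotated to principal axes
  with a deterministic sign convention, so coordinates are comparable across
  runs.
* **Degenerate input.** If all dissimilarities are equal, any configuration
  is equally (un)faithful; the function warns and returns the centred metric
  solution with its stress recorded.

The GAM-fitted depth contours sometimes drawn over such ordinations are a
display device and are deliberately not part of this package's outputs.

## Gradient regressions

Three transformation families of a single-predictor ordinary least-squares
regression are supported, named by the shape they fit: `linear` (`y ~ x`),
`log` (`y ~ ln x`) and `exp` (`ln y ~ x`). "exp" transforms the response —
an exponential decline of density with depth appears as a straight line in
`ln y` — and that interpretation is an explicit, documented choice
(`fit_gradient(..., family = "exp")`); F, p and R² are reported on the
transformed scale where the Gaussian assumptions actually apply.

Model selection uses AICc (second-order small-sample correction, k = 3 for
intercept, slope and residual variance). Because the `exp` family models
`ln y` while the others model `y`, its Gaussian log-likelihood is adjusted
by the log-Jacobian `−Σ ln yᵢ` of the response transform; without that
adjustment cross-family AICc comparison is meaningless. Families whose
domain preconditions fail (non-positive y for `exp`, non-positive x for
`log`) are skipped with a recorded reason rather than fitted nonsense.

Only depth and POC flux are offered as predictors. The collinearity screen
(`correlation_screen()`, |r| ≥ 0.7 flag) exists precisely to justify this:
in surveys laid out along a basin, depth tends to track longitude and flux
tends to track latitude, and regressing on collinear pairs would be
uninterpretable.

## Zonation statistics

Provinces are half-open depth bands (defaults 4,300 m and 4,800 m,
bracketing the regional CCD band). Morphotype overlap counts are
sample-based: a morphotype belongs to a province if it occurs in any BD
sample whose mean depth falls there. This matches totals derived from
rarefied samples rather than raw occurrences. "Rare" means fewer than five
specimens summed over all BD samples — the widest-scope reading of the
conventional threshold. Shallow–deep sharing is counted irrespective of
presence in the transition band.

The boundary sweep slides a single candidate boundary along a 100-m grid,
splits samples into above/below groups and records mean between-group minus
mean within-group Bray–Curtis dissimilarity; the argmax estimates the depth
of strongest replacement. It is a diagnostic, not a changepoint test: no
significance is attached, and with few samples on one side of a candidate
(fewer than `min_group = 2`) the candidate is skipped.

Ridgeline distributions are plain normalized histograms (100-m bins) of a
group's occurrence depths, for groups with more than 50 occurrences; any
smoothing is left to plotting code because "the distribution" should remain
an estimator-free summary of the data.

## The synthetic generator

`synthetic_config()` defines an emulated survey region; its defaults are the
package's study conditions and are not tuned per analysis:

* 14 sites holding 28 geographic locations (1–6 each), on a joint lattice
  from deep north-west (5,250 m, 18° N) to shallow south-east (3,950 m,
  8° N), spanning 3,900–5,300 m.
* POC flux `F(lat, z) = F_export(lat) · (z/100 m)^−0.858`, with export flux
  ramping 15 → 40 gC m⁻² yr⁻¹ from north to south. The 0.858 attenuation
  exponent is the canonical open-ocean Martin value; both are configurable.
* 400 morphotypes with log-series base weights (x = 0.995), so most taxa
  are rare; weights are thinned per site by an occupancy–abundance rule
  (`P(present) = 1 − e^{−w/5}`) and perturbed by a per-site lognormal factor
  (σ = 1.0), giving realistic local richness, site-level dominance shifts
  and compositional turnover between sites.
* Four depth-response classes: `declining` and `increasing` logistic
  profiles with midpoints drawn within ±150 m of the CCD and scale 80 m
  (the programmed community replacement is therefore centred on the CCD),
  `ubiquitous` flat profiles, and `ccd_restricted` taxa (shelled molluscs,
  bryozoans) with a hard zero below the 4,600-m CCD. Because all profiles
  are monotone or flat, no taxon is programmed as transition-exclusive.
* Survey effort of 80 still frames × 20 m² per location; per-frame counts
  Poisson with mean `area · density_scale · F/F_ref` (density_scale = 0.7
  ind m⁻² at the reference flux), placing overall densities inside the
  0.06–1.46 ind m⁻² band reported for comparable abyssal surveys. Poisson
  rather than negative-binomial is the default for analytic tractability of
  the scaling tests; overdispersion can be emulated through the site-level
  lognormal term.
* 30% of specimens are relabelled as identifiable only to a higher taxon,
  mimicking the realistic fraction of records unusable for morphotype-level
  biodiversity work.

The generator returns a `synthetic_truth` object (CCD depth, density–flux
slope, per-location expected densities, the community pool) against which
the recovery tests assert: between-province Bray–Curtis exceeds
within-province, the boundary sweep localises the CCD within one 100-m grid
step, calcifiers never occur below the CCD (exact by construction), and the
exponential density–depth fit recovers the programmed slope sign and
magnitude (the programmed slope is computed from the truth object's
noiseless expected densities, which fold together Martin attenuation and the
latitude–depth covariance of the lattice).

What the generator does **not** emulate — and what passing recovery tests
therefore cannot certify about real data: nodule-cover microhabitat
structure, seamount faunas, real satellite flux fields, spatial
autocorrelation within locations, taxonomic misidentification, and
depth-varying identifiability. Image positions within a location are
degenerate (all frames at the location centre): the pipeline only uses
positions for gridding and flux lookup, and point-clusters guarantee the
programmed location count survives any grid alignment.

## Problem sizes

The test suite and the acceptance script run the full pipeline on the
default region (~34,000 specimens, ~100 BD and ~55 SS samples), NMDS on the
resulting ~100 × 100 dissimilarity matrix with 8 restarts, accumulation
curves with 100 permutations, and property checks with up to 1,000 random
fixtures; the complete suite finishes in about a minute on a single CPU.
These sizes were chosen to exercise every code path at realistic survey
scale while keeping iteration fast.

## Known limitations

* The boundary sweep evaluates a single boundary; the three-province scheme
  is imposed, not inferred, and no changepoint significance is computed.
* NMDS is local search; with pathological dissimilarity structure more
  restarts (`n_restarts`) may be needed than the default.
* Gradient models are single-predictor by design; spatial-error or
  mixed-effects structure is out of scope.
* Coverage-based rarefaction/extrapolation (Chao-type asymptotic richness)
  is intentionally not provided; curves describe sampled effort only.
* The occurrence reader expects one row per specimen with per-image area
  repeated on specimen rows; annotation-tool exports must be flattened to
  that shape first (an alias map absorbs header dialects).
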