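# abyssbio

Bottom-up biogeographic analysis of abyssal seafloor megafauna from seabed
imagery. The package turns raw specimen occurrence tables (one row per
detected animal, with position, depth and a standardized morphotype label)
into specimen-rarefied community samples and asks the macroecological
questions a regional survey of an abyssal plain poses: how do standing
stocks, diversity and community composition change with depth and food
supply, and where do depth-defined biogeographic provinces begin and end?

It is written for benthic ecologists working with ROV/AUV image surveys of
abyssal plains (for example, polymetallic-nodule provinces such as the
Clarion–Clipperton Zone), where the carbonate compensation depth (CCD)
intersects the seafloor and is hypothesized to drive faunal zonation.

## What it computes

* **Survey design** — specimens are projected onto a local 10 × 10 km grid to
  define geographic locations; within each location × 200-m depth bin,
  specimens are resampled without replacement into equally sized replicate
  community samples: a biodiversity set (**BD**, exactly 200
  morphotype-identified specimens per sample) and a standing-stock set
  (**SS**, 450–500 specimens assembled from whole scalable still images so
  that seabed area is well defined).
* **Alpha diversity** — Hill numbers per BD sample: richness
  `S = #{i : x_i > 0}` (order 0) and the exponential Shannon index
  `exp H' = exp(−Σ p_i ln p_i)` (order 1); sample-based morphotype
  accumulation curves (100 seeded sample-order permutations with t-based 95%
  envelopes); province means with 95% confidence intervals.
* **Standing stocks** — faunal density `n / area` (ind m⁻², convertible to
  ind ha⁻¹) per SS sample, for the whole assemblage or any taxon subset.
* **Beta diversity** — Bray–Curtis dissimilarity
  `BC(x, y) = Σ|x'_i − y'_i| / Σ(x'_i + y'_i)` on square-root transformed
  abundances, and a from-scratch non-metric multidimensional scaling
  minimising Kruskal stress-1 with pool-adjacent-violators isotonic
  regression and multiple seeded starts.
* **Gradients** — metric ~ depth / POC-flux regressions under three
  transformation families (`linear`: y~x, `log`: y~ln x, `exp`: ln y~x) with
  small-sample AICc selection (Jacobian-adjusted so families are comparable),
  plus a Pearson collinearity screen over depth, latitude, longitude and POC
  flux.
* **Zonation** — province classification (shallow < 4,300 m, transition
  4,300–4,800 m, deep > 4,800 m, configurable), ridgeline depth distributions
  of dominant higher taxa, morphotype overlap/exclusivity/rarity counts
  between provinces, top-k dominance concentration, and a boundary-sweep
  diagnostic that locates the depth of strongest community replacement.
* **Synthetic data** — a generator that emulates the statistical structure
  the analysis assumes (depth/latitude site lattice, Martin-curve POC flux
  field `F(z) = F_export · (z/100)^−0.858`, hard CCD cut-off for calcifying
  taxa, long-tailed log-series abundance distribution) together with the
  programmed ground truth, so every stage is testable without downloads.

## Worked example

```r
library(abyssbio)

cfg <- synthetic_config()                  # the emulated survey region
gen <- generate_occurrences(cfg, seed = 1)
gen$table
#> <occurrence_table> 33824 specimens on 2240 frames, 23731 identified to morphotype
gen$truth
#> <synthetic_truth> CCD 4600 m; density-flux slope 0.6798 ind m^-2 per gC m^-2 yr^-1; 28 locations

plan <- sampling_plan(seed = 1)
bd <- make_samples(filter_subset(gen$table, "BD"), "BD", plan)
bd
#> <community_samples> 103 samples x 298 taxa (mode: BD)

div <- diversity_estimates(bd)
summary(div$richness)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   55.00   66.50   70.00   69.51   73.00   82.00

d   <- bray_curtis(bd)                     # sqrt-transformed Bray-Curtis
ord <- nmds(d, k = 2, n_restarts = 8, seed = 1)
ord
#> <nmds_ordination> 103 points, k = 2, stress-1 = 0.1604 (converged)

boundary_sweep(bd, d = d)
#> <boundary_sweep> best boundary: 4500 m

prov <- classify_province(bd$meta$mean_depth)
province_summary(div$richness, prov)
#>     province metric_n     mean   ci_low  ci_high
#> 1    shallow       54 69.98148 68.70510 71.25786
#> 2 transition       36 69.91667 67.73680 72.09653
#> 3       deep       13 66.46154 63.66372 69.25935
```

Reading: 33,824 simulated specimens across 28 grid locations rarefy into 103
BD samples of 200 specimens each. Per-sample richness spans 55–82
morphotypes; the NMDS embeds the 103 × 103 Bray–Curtis matrix in two
dimensions at stress 0.16 (a fair representation); the boundary sweep places
the strongest compositional replacement at 4,500 m, one grid step from the
programmed 4,600-m CCD; and province mean richness is statistically
indistinguishable across the boundary (overlapping 95% CIs) even though
composition turns over — richness maintained through taxonomic replacement.

`run_pipeline("out/", seed = 1)` chains all stages and writes every artifact
(samples, metrics, dissimilarity matrix, ordination, fits, zonation tables)
plus a JSON manifest; `inst/scripts/run_pipeline.R` wraps it for the shell.

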