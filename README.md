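# rangekit

Space-use analysis for group-living animal telemetry along a gradient of
association with humans.

Telemetry studies of social species such as banded mongooses (*Mungos
mungo*) ask how much space a group uses, how unevenly it uses it, and what
drives the variation — season, resource richness, patch dispersion, group
size, or access to anthropogenic resources. `rangekit` implements that whole
analysis chain as tested, reusable R functions, together with a
synthetic-data generator that produces ground-truthed telemetry so every
stage can be validated end to end.

## What it computes

* **Utilization distributions** by fixed-kernel density estimation with the
  bivariate biweight kernel K(u) = (3/π)(1 − ‖u‖²)² on per-axis
  unit-variance-standardized fixes. Bandwidths are selected by least-squares
  cross-validation of the normal kernel (log-spaced scan plus golden-section
  refinement of the global minimum) and converted for the biweight kernel by
  the canonical constant A(K) = 35^(1/5) ≈ 2.04. Grids are square-celled with
  75 cells along the shorter axis.
* **Home ranges** as 95% volume contours (exact threshold search over sorted
  cell densities, marching-squares polygons), clipped to dry land, with
  areas in hectares.
* **Dispersion of space use** via the area-probability curve f(x) — the
  proportion of home-range area at probability of use ≥ x, scaled by the
  maximum probability of use — and its integral, the **area-probability
  integral (API)** ∈ (0, 1]: smaller API = more concentrated use.
* **Non-arbitrary core ranges** at the scaled-density threshold where f(x)
  departs farthest from the uniform-use line 1 − x, reported with their
  equivalent volume contour.
* **Diagnostics**: area-observation asymptotes (5 randomized resampling
  orderings, 95% CI within 15% of the final area; a sequential mode detects
  range drift), Schoener's ratio t²/r² with time-to-statistical-independence,
  displacement, and day ranges (days with ≥ 10 fixes spanning ≥ 5 h).
* **Covariates**: a human-association scale (sign-oriented PC1 of
  log-standardized tourist and building densities), building/macrofauna/
  tourist counts and densities inside ranges (published habitat-by-season
  soil-macrofauna densities are embedded), mean nearest-neighbour patch
  dispersion, modal/median group sizes, fecal organic-matter medians, and
  the (after − before)/before fold-change convention.
* **Bayesian models** (JAGS): simple linear regressions under Cauchy(0, 10)/
  Cauchy(0, 2.5) or Normal(0, 10⁶) priors with half-Cauchy(0, 5) residual
  scale, and a robust-t paired-difference model with a diffuse t location
  prior (variance 10⁶ × score variance) plus a skeptical-prior sensitivity
  refit. Summaries: posterior mean β, 95% HPDI, % posterior below/above 0,
  certainty bands (high < 5% tail, moderate 5–10%, uncertain otherwise) with
  odds (1 − tail)/tail (95% ⇒ 19:1, 98% ⇒ 49:1), split-chain PSRF, DIC, and
  posterior-predictive Bayesian p.
* **`runStudy()`** orchestrates the full analog of the field study per group
  and season and `reportStudy()` prints the conventional table (β, HPDI
  LB/UB, %<0, %>0, DIC, HC/MC/U).

## A worked example

Simulate a 9-group cohort along the association gradient and run the study
(scaled-down MCMC; the package default schedule is 3 chains × 3×10⁵
iterations):

```r
library(rangekit)
dat <- simulateStudyData(simConfig(seed = 1))
cfg <- studyConfig(mcmc = list(iterations = 20000, burnin_regression = 1000,
                               burnin_paired = 2000))
res <- runStudy(dat, cfg, seed = 1)
```

Headline metrics and the association/seasonal model rows:

```
median home range: 46 ha | median core: 13 ha (53% contour) | median API: 0.32
PC1 variance explained: 87%
     Response     Predictor  Season n     beta       LB      UB %<0 %>0   DIC Interp
   hr_area_ha           pc1 overall 9 -11.0000 -17.8000 -2.2600  99   1  72.1     HC
 core_area_ha           pc1 overall 9  -3.7900  -6.2500 -0.9930  99   1  54.5     HC
          api           pc1 overall 9  -0.0164  -0.0478  0.0183  86  14 -25.4      U
   hr_area_ha dry_minus_wet  paired 7 -10.5000 -14.6000 -6.2700 100   0  42.8     HC
 core_area_ha dry_minus_wet  paired 7  -1.6900  -3.0900 -0.2280  98   2  27.8     HC
          api dry_minus_wet  paired 7   0.0339  -0.0255  0.0912  10  90 -16.8      U
```

Reading the output: home-range and core area shrink with increasing
association with humans (negative slopes on PC1, high certainty, 19:1 or
better odds), and within the 7 synanthropic groups dry-season ranges and
cores are smaller than wet-season ones (negative paired differences, high
certainty) — the seasonal reversal the generator builds in. The paired API
row is uncertain here because the generator scales ranges without changing
their internal concentration, so no API difference exists to detect.
`res$records` holds the per-group × season table (areas, API, core contour,
bandwidths, covariates); `res$manifest` records the seed, config echo,
dropped group-seasons and output hashes.

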