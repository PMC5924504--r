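---
title: "Kernel home ranges, the area-probability integral, and Bayesian drivers of space use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel home ranges, the area-probability integral, and Bayesian drivers of space use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rangekit)
```

## The problem

Group-living animals such as banded mongooses (*Mungos mungo*) use space in
ways that reflect trade-offs between resource acquisition and the costs of
movement. Along a gradient of association with humans — from groups ranging
entirely in protected woodland to groups denning in town lodges — both the
amount of space used and how evenly it is used can change, and the direction
of seasonal effects can even reverse between synanthropic and apoanthropic
groups. `rangekit` implements the full analysis chain for such a study:
utilization distributions and volume-contour home ranges from telemetry
fixes, a dispersion-of-space-use statistic (the area-probability integral),
non-arbitrary core ranges, movement and independence diagnostics, resource
covariates, and Bayesian models of space-use drivers. A synthetic-data module
generates ground-truthed telemetry so every stage is testable without field
data.

## Utilization distributions

Fixes are planar projected coordinates in metres (UTM-like); the package does
no geodesic computation. Each axis is standardized to unit variance
(per-axis, not pooled — both conventions appear in the kernel home-range
literature; per-axis is the one used by the ABODE-style workflow this follows
and is what `standardizeFixes()` implements), and a single scalar bandwidth
is selected in standardized space.

**Bandwidth.** The least-squares cross-validation (LSCV) score of the
bivariate normal kernel is

$$CV(h) = \frac{1}{4\pi n h^2} + \frac{2}{n^2h^2}\sum_{i<j}
  \left[\tfrac12\,\phi_2\!\left(\tfrac{d_{ij}}{h\sqrt2}\right)
        - 2\,\phi_2\!\left(\tfrac{d_{ij}}{h}\right)\right],$$

with $\phi_2(u) = e^{-u^2/2}/2\pi$ and $d_{ij}$ the pairwise distances of the
standardized fixes. LSCV scores can be multimodal, so `lscvBandwidth()` first
scans 60 log-spaced bandwidths over a bracket of 0.05–4 times the normal
reference bandwidth $n^{-1/6}$ and then refines the global scan minimum by
golden-section search; a minimum on a bracket edge widens the bracket and
retries. For more than $5\times10^6$ pairs the squared distances are binned
(20 000 bins, exact within-bin means) before scoring — the score is a smooth
functional of the pair-distance distribution, so the approximation error is
far below the optimizer's resolution while evaluation becomes $O(\text{bins})$.

The LSCV optimum is selected for the normal kernel and converted for the
biweight kernel by the canonical constant
$A(K) = (R(K)/\mu_2(K)^2)^{1/5} = 35^{1/5} \approx 2.04$; the density itself
uses the bivariate biweight $K(u) = \tfrac{3}{\pi}(1-\lVert u\rVert^2)^2$ on
the unit disc, a compact-support kernel.

**Grid.** Densities are evaluated at the centres of square cells, 75 cells
along the shorter axis by default, over the fix bounding box padded by 3
biweight bandwidths per axis so that no kernel mass is truncated (the padding
multiplier is configurable). Cell masses are normalized to sum to one and the
`UtilizationDistribution` object stores mass per cell.

## Isopleths, clipping, and areas

A volume contour at level $p$ uses the highest density threshold $t$ such
that cells with density $\ge t$ hold at least $p/100$ of the UD mass; the
threshold is found exactly by sorting cell densities rather than by
iterative bisection. Contour polygons come from marching squares with linear
interpolation (`grDevices::contourLines`), nudged infinitesimally below $t$
so threshold cells are enclosed.

Areas are measured on the grid: the number of qualifying cells times the cell
area, reported in hectares (m²/10⁴). Clipping to dry land is also done at
cell level — a cell belongs to the range if its centre is on land — and the
clipped contour is extracted from the land-masked density field. Both the
clipped (headline) and unclipped areas are retained, since it is ambiguous
whether mass should be renormalized before or after clipping; the package
reports post-clip areas, matching the convention of clipping contours to dry
land, and never renormalizes after clipping. Cell-level clipping converges to
polygon clipping at the grid resolution; with 75 cells on the short axis the
residual discretization error is well under the tolerances used anywhere
downstream.

Degenerate note: on surfaces with exactly tied densities (e.g. symmetric
analytic test grids) all tied cells at the threshold enter the range, so the
enclosed mass can exceed the requested level by more than one cell's mass;
on estimated surfaces ties have probability zero.

## Area-probability curves, the API, and core ranges

Within the home range, scale cell densities by their maximum. The
area-probability curve is
$f(x) = \Pr(\text{scaled density} \ge x)$ over home-range area, evaluated on
a 1001-point lattice of $x \in [0,1]$; $f$ is non-increasing with $f(0)=1$.
The area-probability integral is $\mathrm{API} = \int_0^1 f(x)\,dx$
(trapezoidal rule). Both axes are proportions, so the API lies in $(0,1]$:
uniform use gives exactly 1, and smaller values mean use concentrated into a
smaller proportion of the range (for any exceedance curve the integral equals
the mean scaled density, which is what the brute-force oracle in the test
suite exploits). Equivalent percent-scale conventions differ only by axis
scaling.

The core range is delineated non-arbitrarily from the same curve: the
threshold $x^\ast$ maximizes the absolute deviation between $f$ and the
uniform-use reference line $f_{\mathrm{ref}}(x) = 1-x$. Concentrated
unimodal use puts the curve below the line (for a bivariate normal the
maximizer is $x^\ast = 2/\chi^2_{2,0.95} \approx 0.334$, an equivalent volume
contour of ~67%); stepped multimodal use can put it above, which is why the
absolute deviation is used. Ties are broken toward larger $x$, the more
concentrated core. A slope-criterion alternative (first $x$ where the curve's
slope reaches $-1$; identical to the maximum deviation for convex curves) is
selectable via `core_rule = "slope"`. Exactly uniform use has no core; the
function signals this with an `NA` result and a message, not an error. The
core's *equivalent volume contour* is the UD mass inside the core times 100,
which is how core concentrations are compared across groups.

## Movement and independence diagnostics

* **Schoener's ratio** $t^2/r^2$ — mean squared successive-fix distance over
  mean squared distance from the activity centre — is about 2 under serial
  independence. `schoenerTTSI()` thins a track to candidate inter-fix
  intervals and reports the shortest interval from which the ratio (at that
  and every longer candidate) exceeds 2; "consistently" is interpreted as
  "at the candidate and all larger candidates".
* **Asymptote analysis** resamples fixes in 5 random orderings, re-estimates
  the range area at sizes step, 2·step, …, n, and puts a normal 95% CI
  across orderings at each size; the asymptote is the smallest size from
  which both CI bounds stay within 15% of the full-sample area at every
  larger size. Random reordering cannot detect range drift (any random
  subsample is representative of the whole track), so a sequential mode
  accumulates fixes in time order as the drift diagnostic; a drifting track
  then never reaches an asymptote.
* **Displacement** is the distance from the group's first fix of the study to
  each later fix. **Day range** is the summed consecutive-fix distance within
  a day, in km, counted only for days with at least 10 fixes spanning at
  least 5 h.

## Covariates

* **Human-association scale:** log-transform (with a +1 offset so the zero
  densities of unassociated groups stay scored; the offset is configurable)
  and standardize tourist bed-night density and building density, take an
  SVD principal-component decomposition, and orient PC1 so that larger
  scores mean more association with humans. Scores are zero-mean, and PC1's
  variance explained is reported.
* **Resource densities:** building count is points inside the range (cell
  membership, consistent with how areas are measured); macrofauna counts
  multiply each habitat's area inside the range by its published per-season
  soil-macrofauna density (`macrofaunaDensities()` embeds the five published
  habitat-by-season values, per m² to 20 cm depth), so a single-habitat range
  recovers the published density exactly. Densities always recompute from
  counts and areas. Core-range variants measure the same quantities inside
  the core polygon set.
* **Patch dispersion:** mean nearest-neighbour distance among trees and
  buildings (pooled) inside the range; per-class values are also returned.
* **Fold change:** the convention for seasonal statements is
  (after − before)/before; the sign gives direction, the magnitude is what
  "increased/decreased by X-fold" reports.
* **Group size:** monthly modal adult count (ties broken to the smaller
  mode, logged), seasonal size = median of monthly modes; opportunistically
  counted groups use the median of raw counts.
* **Fecal organic matter:** group medians overall and per season; laboratory
  ashing is out of scope, percentages are inputs.

## Bayesian inference

Three model families, all sampled with JAGS (`rjags`) and summarized by the
package's own routines:

* `regression_cauchy` — simple linear regression with Cauchy(0, 10) intercept
  and Cauchy(0, 2.5) slope priors (the association-gradient battery). The
  residual-scale prior is not pinned down by the study design; the package
  uses half-Cauchy(0, 5), the same residual prior as the other regression
  family.
* `regression_normal` — Normal(0, variance 10⁶) intercept and slope,
  half-Cauchy(0, 5) residual scale (the seasonal driver battery). "Cauchy"
  residual priors are taken as half-Cauchy since scales are positive.
* `paired_difference` — a one-sample location-scale model on paired
  difference scores with a robust t likelihood; the degrees of freedom get a
  shifted-exponential prior (mean 30), the location a t prior (3 df) centred
  on mean(d) with variance exactly 10⁶ × var(d), and the scale a broad
  uniform. A sensitivity refit under the skeptical prior t(0, variance 1) is
  always reported alongside; for well-separated effects it does not change
  the certainty band. A normal likelihood is available by flag.

The default schedule is 3 chains, burn-ins of 10³ (regressions) or 3×10³
(paired differences), and 3×10⁵ pooled iterations; the test suite and the
examples below run scaled-down chains (2–2×10⁴ iterations) since the checks
they make are sign/coverage properties, not tail quantiles. Numerical detail:
the predictor is centred inside the sampler (decorrelating intercept and
slope so JAGS's single-site updates mix; the slope posterior is unaffected,
and the intercept prior applies to the centred intercept).

Summaries per fit: posterior mean effect β; the 95% highest posterior density
interval by the sorted-window algorithm; the percent of posterior below and
above zero; a certainty band (high if the smaller tail is < 5%, moderate if
5–10%, uncertain otherwise) with odds (1 − tail)/tail, so 95% posterior mass
on one side is 19:1 and 98% is 49:1; split-chain potential scale reduction
factors per parameter (a fit is retried with a longer burn-in and then
reported as a convergence error if any PSRF ≥ 1.1); DIC computed as
$\bar D + p_D$ with $p_D = \bar D - D(\bar\theta)$; and a posterior-predictive
Bayesian p for the mean-absolute-residual discrepancy, with (0.05, 0.95)
read as adequate fit.

## The synthetic-data generator

`simulateStudyData()` emulates the study conditions with full ground truth:

* **Movement** is i.i.d. draws from a den-anchored mixture of bivariate
  normals (3 dens per group, scattered in proportion to the group's spread),
  *not* a correlated walk — this keeps the true UD, its 95%-mass area and its
  API analytically/numerically exact (`trueMixtureStats()`). An AR(1) mode on
  the positional deviations exists solely to exercise the independence
  diagnostics.
* **Association gradient:** 9 groups, association levels 0–1 with two
  unassociated groups; the per-axis spread is 150 m at association 0,
  shrinking as $e^{-0.55a}$ so the most associated group's range area is
  about a third of an unassociated group's — the magnitude of the contrast
  observed between synanthropic and apoanthropic groups.
* **Seasonal reversal:** synanthropic groups contract in the dry season
  (spread scale 0.82 vs 1.0 wet, reproducing the ~1.5-fold wet:dry area
  ratio reported for such groups, seasonal medians 40 vs 27 ha) while
  apoanthropic groups expand (1.15 vs 1.0, from seasonal ranges of 124 vs
  94 ha). Transition months use the mean scale.
* **Schedule:** one first-sighting fix per day at a random daylight minute,
  plus a 31-fix follow day every 10 days; 15 m Gaussian observation noise
  (the typical spread of a group around its centre). Timestamps are minute
  precision, UTC.
* **Landscape:** buildings as a clustered point process whose expected count
  scales with association (association 0 ⇒ none); independent clustered
  trees; habitat strips cycling the five published classes; a river strip of
  non-land along the northern edge; one lodge (with bed nights growing with
  association) and one refuse site per associated group.
* **Covariates:** fecal organic matter rises with association
  (60% + 25·a, ~30 samples per group), group size is unrelated to
  association, and `simulateCohort()` additionally provides a cheap
  record-level generator with linear effects (true slopes recorded) for
  calibration and coverage experiments.

What the generator does *not* emulate: collective decision-making and
cohesion dynamics, serial correlation of real movement (except the AR(1)
switch), GPS error structure, habitat-selective movement, and den switching
in time. Passing tests therefore demonstrate that the estimators recover
truth under the stated statistical structure, not that real mongoose data
meet that structure.

## Problem sizes and numerical choices in the tests

The test suite runs the full pipeline on 9-group cohorts of roughly 750
fixes per group (a 6-month window), 20 end-to-end replicates for the
sign-structure recovery check, 200 replicates for false-high-certainty
calibration at true slope 0, and 100 cohorts for HPDI coverage; chains are
scaled down to 2–6×10³ iterations for these property checks while the
package default remains 3×10⁵. Oracles are independent of the code paths they
check: dense-grid LSCV search, closed-form Gaussian isopleth areas and
area-probability curves, million-point quadrature for the API,
brute-force nearest-neighbour scans, closed-form Schoener values, classical
least-squares for the conjugate regression case, and `coda` for HPDI/PSRF
cross-checks.

## Known limitations

* Geometry is grid- and cell-based; there is no exact polygon overlay, and
  areas inherit the grid resolution (configurable).
* Polygon repair handles simple self-intersections (bowties); pathological
  multi-loop rings may fail with a geometry error.
* LSCV is known to undersmooth for clumped fixes; the bracket guard reports
  edge solutions but no alternative selector (e.g. plug-in) is provided.
* The paired-difference likelihood follows the robust-estimation convention
  (t likelihood, shifted-exponential df prior); the exact likelihood used in
  any given prior study may differ in detail, which is why the normal
  likelihood and the skeptical prior are both one flag away.
* Simple regressions only — one predictor per model, matching the study
  design this package mirrors.

## A worked run

```{r example, eval = FALSE}
dat <- simulateStudyData(simConfig(seed = 1))
cfg <- studyConfig(mcmc = list(iterations = 20000))
res <- runStudy(dat, cfg, seed = 1, outDir = "study_out")
reportStudy(res)
```

`res$records` holds one row per group and season (areas in ha, API, core
contour, covariates); `res$posteriors` one row per fitted model with β, HPDI
bounds, tail percentages, DIC and the HC/MC/U interpretation code;
`res$manifest` the seed, config echo, dropped groups, any skipped model fits,
and output-file hashes.
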