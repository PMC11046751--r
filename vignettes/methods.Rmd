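---
title: "Methods: from GPS tracks to seasonal predator-prey overlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from GPS tracks to seasonal predator-prey overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, the estimators, and the numerical
choices behind the pipeline, in the order the stages run. Code chunks are
illustrative and not evaluated when the vignette is built.

## The question and the pipeline

The package asks whether a territorial predator (wolves) tracks the
seasonal redistribution of migratory ungulate prey (deer, moose): does the
spatial overlap between wolf seasonal ranges and prey seasonal
distributions increase during prey migration? The pipeline runs

1. synthetic population simulation (with a ground-truth ledger),
2. track quality control,
3. movement-strategy classification and migration timing,
4. season delineation from the timing quartiles,
5. Brownian bridge occurrence distributions per animal-season-year,
6. hierarchical population distributions and the migration corridor,
7. a mechanistic range-shift test on each predator, and
8. proportional-overlap records, logit-linear models, and rank tests.

`run_pipeline(pipeline_config(), seed)` executes all of it; the
`analysis/` scripts run the same stages one at a time with text outputs.

## Synthetic tracks (what the generator does and does not emulate)

Real collar data for this question are not public, so the package carries
its own generator. Each animal is an Ornstein-Uhlenbeck (OU) process
around a piecewise-linear range-center path:

* **Residents** keep one center. **Migratory** animals hold 2-3 centers
  and move between them on scheduled departure days (spring days drawn
  with a small SD, default N(60, 3) in days from 13 February; fall wide,
  N(257, 12)), traveling at `transit_speed` (deer 100 m/h) through shared
  corridor waypoints. **Nomads** visit 4+ centers at irregular intervals
  with no repeated back-shift between the same two centers.
* The OU deviation has stationary SD `range_sd` (deer 600 m, moose 800 m,
  wolves 2500 m; floaters 6500 m) and relaxation timescale
  `ou_timescale` (deer 12 h, wolves 8 h), discretized exactly as an AR(1)
  at the fix interval (4 h).
* Wolves can shift within-territory intensity toward the deer corridor in
  fall (`wolf_fall_shift`, 0 by default: the stationary null regime).
* Mortality appends a terminal stationary jittered cluster; fixes drop
  out i.i.d. with `dropout_prob`.

The generator emulates *central-place seasonal movement with scheduled
transits*; it does not emulate habitat selection, terrain, day-night
cycles, collar duty cycling, or interaction between animals. Every
simulation records a truth ledger (strategies, departure/arrival times,
centers, mortality) used by the recovery tests.

## Quality control

Per track, in order: terminal-cluster mortality censoring (final run
spanning < 50 m for at least 48 h is cut), regularization to the 4-h grid
(nearest fix within a 1-h snap window), an iterative > 10.8 km/h speed
filter (the later fix of an implausible step is removed until none
remain), and a spike filter removing fixes whose first passage time
through a 300-m circle is at most 1 h *and* whose turning angle lies in
the 179-181 degree band (out-and-back spikes). First passage times use
linear interpolation of the circle crossings and are censored (NA) when
the track ends inside the circle.

## Movement classification and event timing

Home-range occupancy is detected without fitting a movement model:

* A fix is *settled* when all positions in its surrounding 48-h window
  stay within half the species' separation scale of the window mean.
* Settled fixes are clustered (average-linkage, tree cut at the
  separation scale: deer 2.5 km, moose 3.2 km, wolves 10 km - roughly
  four positional SDs, so territorial predators need a much larger
  scale), every fix is assigned to its nearest center within the
  separation radius (otherwise transit), and maximal temporal runs form
  segments: at least 30 days of dwell makes a home-range segment, shorter
  occupied runs are stopovers.
* One range = resident; movement between 2-3 ranges = migratory; 4+
  ranges with no repeated back-shift pair = nomadic; spans under 60 days
  = unknown.

A migration event is a transition between ranges in different clusters.
The raw boundary (last fix assigned to the source cluster) is biased: the
animal only leaves the assignment radius `sep` about `sep / speed` after
its range center starts moving (~25 h at deer defaults), and mirrors this
at arrival. `migration_events()` therefore backcasts: it takes the times
at which the 3-fix-smoothed radial distance from the source (target)
centroid crosses `sep` and `1.4 * sep` - both inside the first (last) leg
of the travel path, where radial distance grows at the travel speed
regardless of heading - and extrapolates linearly to radius zero. Two
residual biases largely cancel (the animal trails its moving center by
part of its autocorrelation timescale: late; noise makes the first
sustained crossing fire slightly early). Corrections are clamped to the
known direction and scale of the raw bias (<= 3 days). In simulation this
keeps population timing quartiles within ~0.4 days of the generating
events, versus ~1 day raw.

Timing quantiles are empirical with linear interpolation (R type 7) on
day-of-monitoring-year (origin 13 February). Season windows follow the
quartile rule: spring migration spans the 25% departure to the 75%
arrival quartile of spring events; fall likewise; summer and winter fill
the gaps on a 365-day template (29 February folds into 28 February).

## Brownian bridge occurrence distributions

Between consecutive fixes at most 9 h apart (longer gaps are skipped),
the animal is modeled as a Brownian bridge pinned at the observed
endpoints, with motion variance $\sigma^2_m$ (m^2/h) and i.i.d. GPS error
SD $\delta$ = 20 m per coordinate. At fractional time $\alpha$ along a
segment of duration $T$ hours the position is normal around the
connecting line with per-coordinate variance

$$T\alpha(1-\alpha)\,\sigma^2_m + \left[(1-\alpha)^2 + \alpha^2\right]\delta^2.$$

$\sigma^2_m$ is estimated by leave-one-out maximum likelihood: every
even-indexed fix is predicted from its neighbors under the bridge model
and the product likelihood is maximized (log-grid bracket followed by
`optimize`). The occurrence surface integrates the bridge density over
time - Gauss-Legendre quadrature with 10 nodes per segment (20 in the
oracle tests), segments weighted by duration - and accumulates each
node's separable 2-D Gaussian into 50-m cells by exact 1-D normal
integrals over a +/- 4.5 SD window (an Rcpp kernel). Each raster carries
its own grid whose origin is snapped to the shared 50-m lattice, so later
merges are exact integer-offset block sums, never resampling. Total mass
is normalized to 1 within 1e-6; against a 100,000-path Monte-Carlo bridge
oracle the max absolute cell error is ~2e-4.

## Population distributions, corridor, contours

Population surfaces average hierarchically - individuals within a
season-year, season-years within a year, years within the population - so
years weigh equally regardless of how many animals were collared. Five
populations (wolf, moose, all deer, migratory deer, resident deer) by
four seasons, plus the corridor: the per-year mean of the migratory-deer
spring and fall season-year surfaces, then the across-year mean; 21
distributions in total.

The 95% contour takes cells in decreasing density until the level is
reached. Ties at the cutoff density are resolved minimally and
deterministically (row-major order), so a uniform 10 x 10 surface at
level 0.95 yields exactly 95 cells; `ties = "all"` admits every
tied cell instead (mass may then exceed the level). The minimal rule is
the default because it reproduces the exact-area worked example used in
the tests. Contour similarity between two regions divides the
intersection area by the smaller region's area (Cardillo-Warren style;
`union` and `mean` denominators are options).

## Mechanistic range-shift analysis

Each predator track is tested for a range shift under the migratory
white-noise model: positions are independent bivariate normals with SD
$\sigma$ about a mean that sits at $\mu_1$, moves linearly to $\mu_2$
between $t_1$ and $t_1 + dt$, and stays. For fixed $(t_1, dt)$ the
remaining parameters have closed forms, so fitting is a bounded 2-D
optimization (L-BFGS-B, 5 jittered restarts). Significance is a
likelihood-ratio test against the single-range null, chi-squared with
df = 4 (the difference in free parameters); CIs for $t_1$ and $dt$ come
from the profile likelihood at the chi-squared(1) cutoff.

Two calibration choices matter:

* **Thinning.** The white-noise model assumes independent positions;
  4-h territorial fixes are strongly autocorrelated, which inflates the
  LRT badly (every stationary wolf tests significant). The pipeline thins
  predator tracks to 48-h fixes first, which restores near-independence
  at the OU timescales used here.
* **Candidate cap.** The 3-cluster scan proposes boundaries that look
  most shift-like by construction. Refitting from many of them and
  keeping the best likelihood while using the per-fit chi-squared
  reference is anticonservative: with a cap of 6 candidates the measured
  type-I error was 6.6% (1000 stationary replicates); with a single
  arbitrary candidate, 1.5%. The default cap of 3 measured 4.5%,
  consistent with the nominal 5%, with power 100/100 and CI coverage
  20/20 at an 8-sigma shift (n = 400). The cap was calibrated on seed
  blocks disjoint from every test in the suite.

## Overlap records and statistics

Wolves with at least 5% of fixes inside the corridor 95% contour are
retained; each wolf-season with at least 50 locations contributes one
record per prey distribution: proportional overlap = area(wolf seasonal
95% UD intersect prey seasonal 95% contour) / area(wolf UD), computed on
cell masks of the shared lattice, so the geometry is exact. Proportions
are capped into [0.025, 0.975] before the logit (so 0 and 1 stay finite).

Per prey, an ordinary linear model `logit ~ season + sex + pack` uses
winter / female / floater (FL) as reference levels; wolves whose
year-round 95% range exceeds 561 km^2 are re-labeled floaters. Aliased
covariates make the fit fail loudly with the offending term named; the
pipeline-level wrapper retries with a reduced covariate set (sex + pack,
then pack, sex, none) because tiny demonstration worlds can alias sex
with pack. Seasonal contrasts are also tested with Mann-Whitney tests:
midranks, exact two-sided p by dynamic programming over the doubled
midranks whenever $n_A n_B \le 400$ (mathematically identical to full
enumeration, which is infeasible to run literally at e.g. 20 vs 20), and
the tie-corrected normal approximation with continuity correction
otherwise.

## Problem sizes and runtime

The default configuration (46 animals, 2 years, 4-h fixes, 50-m rasters)
runs the full pipeline in a few minutes on one CPU; the test suite's
end-to-end worlds use one year and 150-m rasters (~20 s per replicate).
These sizes are this package's own desk-scale choices: they keep every
stage's statistical behavior measurable (type-I error, power, recovery
error) without collar-study data volumes.

## Limitations

* The generator's simplifications (no habitat, no interaction, constant
  transit speed) mean recovery results certify the estimators, not field
  performance.
* The white-noise range-shift test depends on the thinning interval;
  residual autocorrelation at daily spacing still inflates it slightly.
* Season windows derive from deer timing only, because deer drive the
  migration pulse; moose events are classified but do not move the
  windows.
* All geometry is planar meters with no CRS machinery; inputs in a
  projected metric CRS are assumed.
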