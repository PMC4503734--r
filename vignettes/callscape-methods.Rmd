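---
title: "Territory isopleths and audience-targeted vocal advertisement: methods"
author: "callscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Territory isopleths and audience-targeted vocal advertisement: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(callscape)
```

## The scientific problem

In many territorial, group-living birds and mammals a single dominant pair
monopolises reproduction, so subordinates seeking to breed must either
prospect — leave the group to visit neighbours, which carries measurable
body-condition costs — or advertise from inside the natal territory.
`callscape` implements a complete spatial pipeline for asking whether
subordinate loud-calls are *placed* strategically: on territory edges, near
unrelated neighbouring groups, and specifically near the neighbours holding
the most potential breeding partners (unrelated, opposite-sex adults), and
whether calling days carry a body-mass cost.

The pipeline has four stages:

1. **Territory estimation** from group GPS fixes with the adaptive
   sphere-of-influence local convex hull (a-LoCoH) and nested 50/75/95 %
   density isopleths.
2. **Band analysis**: do calls follow group movement? Observed calls per
   band are tested against the movement-proportional expectations
   0.5 / 0.25 / 0.20 of the total.
3. **Border analysis**: 100 m buffer zones around neighbouring
   territories define *inclusion areas*; observed calls there are compared
   with area-proportional expectations, split by neighbour relatedness and
   composition.
4. **Cost analysis**: daily mass change on heavy calling days
   (≥ 6 bouts) paired with nearby non-calling days.

## Territory estimation (a-LoCoH)

For each fix $p_i$ the *local hull* is the convex hull of $p_i$ together
with the maximal prefix of its nearest neighbours, taken in order of
ascending distance, whose cumulative distance to $p_i$ does not exceed the
budget $a$ (metres). Hulls are sorted by ascending area — ties broken by
descending member count, then root index, so output is deterministic — and
unioned in that order; the isopleth at level $q$ is the union of the
minimal prefix covering at least $\lceil q\,n\rceil$ fixes.

Decisions a user should know about:

* **Coverage is boundary-inclusive** ("encompasses" is read as a closed
  polygon), and duplicate fixes each count — duplicates encode utilisation
  intensity.
* **The default budget** is the maximum pairwise distance between fixes,
  the customary starting heuristic for this estimator. It produces
  deliberately coarse hulls; analyses that need empirical band coverage
  close to the nominal 50/75/95 % (e.g. the simulation studies below) use
  a fraction of it (`a_fraction = 0.25`), which keeps the coverage
  overshoot within about 1 % of nominal. The budget actually used is
  recorded in every fit and in the report provenance.
* **Degenerate hulls** (fewer than three distinct, non-collinear members)
  have area zero and cover exactly their member fixes; all-identical fixes
  are an error.
* **Numerical geometry.** Polygon unions, intersections and Minkowski
  buffers are exact-arithmetic polygon clipping; outputs are passed
  through an iterated simplification step so rings are strictly simple
  and signed-area sums are exact. Point-in-polygon tests carry a
  10^-4^ m boundary tolerance: clipped polygons snap vertices at
  sub-micrometre resolution, and without the tolerance fixes lying
  exactly on hull vertices would be misclassified — the tolerance is
  four orders of magnitude below GPS accuracy.

`locoh()` returns a classed fit with `print`, `summary`, `plot` and
`predict` methods; `predict()` classifies new points into the bands
`core50`, `band50_75`, `band75_95`, `outside95` (innermost containing
isopleth, boundary inclusive).

```{r locoh-demo}
set.seed(1)
fx <- simulate_movement(c(0, 0), 300, theta = 0.15, sigma = 120, seed = 1)
fit <- locoh(fx[, c("x", "y")], a = 0.25 * choose_a(as.matrix(fx[, c("x", "y")])),
             group_id = "demo")
summary(fit)
```

## Null models and test shapes

**Movement null (band test).** Expected band counts are
$(0.5, 0.25, 0.20) \times$ total calls, deliberately *not* renormalised:
they sum to 0.95 of the total because about 5 % of movement lies outside
the 95 % isopleth. The three-category test therefore has df = 2, and
calls outside the 95 % isopleth are reported separately rather than
entering the test. Counts are pooled across eligible callers
(≥ 10 located calls in a season, inclusive) before testing; both the
call-level and the deduplicated location-level versions are always
computed, since repeated calls from one perch are not independent.

**Area-proportional null (border test).** For a focal caller with total
calls $C$, focal 95 % isopleth area $A$ (ha) and inclusion area $A_b$
(ha) at one neighbour's border, the expected count is $C/A \times A_b$.
Pooled related-border and unrelated-border observed counts are tested
against their pooled expectations with two categories (df = 1). A call
inside two overlapping neighbour buffers counts toward both neighbours
and is flagged in the log.

**Paired comparisons.** Per caller, the neighbour maximising/minimising
the relevant composition metric (adults; potential partners; same-sex
unrelated adults — the control) is selected, ties broken by
lexicographically smallest group id and logged; the related/unrelated
comparison instead pools counts and areas within each relatedness class.
Rates are per hectare of inclusion area. Two-sided paired *t* tests with
df = n − 1 throughout; the chi-squared layer uses the plain Pearson
statistic with no continuity correction.

**Relatedness** is the additive (tabular-method) relationship from the
behavioural pedigree; unknown parents are founders. A neighbour group is
*related* if any current dominant has $r \ge 0.25$ with the caller
(inclusive); a *potential partner* is an unrelated ($r < 0.25$),
opposite-sex adult (≥ 365 days post-hatch, inclusive). Individuals of
unknown sex are excluded from partner and same-sex counts and reported.

**Mass cost.** A calling day (≥ 6 bouts) is paired with the
nearest-in-time zero-bout day within 14 days; one pair per individual
(smallest gap, earliest on ties); mass change is session end minus start.

## The synthetic-data generator

No field data accompany the analysis, so the generator emulates the study
system at the protocol's scales and is itself first-class, tested code:

* **Movement**: a discrete mean-reverting (AR(1)) walk,
  $x_{t+1} = x_t + \theta(c - x_t) + \sigma\varepsilon_t$, 300 fixes per
  group-season at 15-minute stamps. Defaults $\theta = 0.15$,
  $\sigma = 120$ m give a stationary spread
  $\sigma/\sqrt{\theta(2-\theta)} \approx 228$ m and 95 % territories of
  a few tens of hectares — the right order for a medium-sized Kalahari
  passerine — and the simplest process producing a dense centre with
  nested isopleths.
* **Landscape**: territory centres on a grid (default spacing 800 m; a
  `grid_ncol` option yields linear chains), groups of 2–15 with one
  dominant pair. The spacing is calibrated to the movement model: at the
  default $\theta, \sigma$ the fitted 95 % isopleth has an effective
  radius near 300 m, and 800 m is the spacing at which adjacent
  territories reliably come within the 100 m buffer — the generator must
  produce neighbours that genuinely share borders, or border-placed
  calls silently degenerate to the movement null. The price is that the
  buffer is ~17 % of a territory diameter (larger than the ~5 % typical
  of the field system); matching that ratio would need a much
  longer-range walk that mixes poorly at 300 fixes;
  subordinates are offspring of their group's dominants. A configurable
  fraction of adjacent pairs is made *related* by replacing one group's
  dominant female with a dispersed offspring of the other group's
  dominant pair — the realistic dispersal route, giving $r = 0.5$ to the
  other group's subordinates.
* **Calls**: each of 10–38 calls is, with probability `border_bias`,
  placed uniformly in an unrelated neighbour's inclusion area chosen
  with probability $\propto (1 + \text{partners})^{\gamma}$, and
  otherwise at a uniformly chosen movement fix (the movement null).
* **Weights**: daily mass change = baseline gain + calling effect ×
  (calling day) + noise, with control days 2–11 days from calling days.

What the generator does *not* emulate: observation-session clustering of
calls (the field data's main non-independence, which the location-level
analyses mitigate), seasonal drift in mass gain, habitat heterogeneity,
and territory drift within a season. Passing recovery tests therefore
shows the pipeline recovers effects under idealised sampling, not that
field estimates are unbiased.

## Parameter-recovery experiments

Problem sizes were chosen to exercise the full pipeline on one CPU:

* **Type-I control**: 1000 replicates; each simulates one group-season
  (300 fixes), fits the territory (`a_fraction = 0.25`), places
  10 × 25 calls at uniformly chosen fixes and runs the pooled band test.
  The unnormalised three-band expectation makes the statistic's null mean
  2.05 rather than 2, so rejection sits slightly above the nominal 5 %.
* **Power**: 200 replicates (10 two-group landscapes × 20 call
  replicates) with `border_bias = 0.5`, 10 callers × 25 calls.
* **Partner-direction recovery**: 50 replicates of a six-territory
  linear chain (spacing 650 m) with a repeating 3/8/13-member
  composition gradient, $\gamma = 3$, and movement bounded at a 360 m
  territory radius. Three design points matter here. First, the chain
  keeps each caller's two border strips geometrically comparable: the
  planted preference acts on call *counts*, the comparison is on
  per-hectare *rates*, and a tiny corner border can otherwise invert the
  rate direction legitimately. Second, the gradient guarantees adjacent
  neighbours actually differ in composition — with random sizes the
  neighbours' partner counts are frequently near-tied (and a period-2
  alternation makes every interior caller's two neighbours *equal*), in
  which case there is no planted direction to recover. Third, the
  bounded radius (the reflecting `max_radius` option, emulating a
  defended boundary) makes adjacent pairs always share a substantial
  border while territories two steps apart never touch: with unbounded
  walks, rare far excursions create ~0.05 ha accidental borders between
  distant groups, and a handful of calls in such a sliver yields a
  per-hectare rate two orders of magnitude above every legitimate
  border, dominating the paired mean in whichever direction it lands.
* **Mass-cost power**: 2000 replicates of 8 individuals with a planted
  −2 g calling effect and 1 g daily noise, against the closed-form
  noncentral-t power with difference SD $\sqrt{2}$ g (both days carry
  independent noise).

## Interfaces

The package is function-first: `simulate_dataset()`, `locoh()`,
`run_audience_analysis()` and `write_report()` compose the
simulate → territory → audience → stats → report chain, and
`scripts/acceptance.R` is the reproducible end-to-end entry point; no
separate shell binary is shipped. Input files are delimited text with a
header and a column-dialect mapping; polygons are written as RFC 7946
GeoJSON with `group_id`, `level`, `area_ha` and provenance properties.
Coordinates must be planar metres — any metric projection is fine at a
field site a few kilometres across (`lonlat_to_utm()` is provided), and
dates are compared at day resolution.

## Known limitations

* Session-level non-independence of calls is not modelled (no
  mixed-effects layer); the location-level analyses are the mitigation.
* Relatedness is pedigree-based only; no marker-based estimator and no
  inbreeding adjustment beyond the tabular recursion.
* Planar geometry only; geodesic areas are out of scope.
* The related/unrelated chi-squared pools callers (matching the df = 1
  design); a per-caller hierarchical version is future work.
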