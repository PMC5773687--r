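---
title: "Ensemble range-shift modelling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble range-shift modelling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmrange)
```

## Scope

`sdmrange` estimates how the climatically suitable range of a species —
typically an invasive plant known only from presence records — will shift
under future climate scenarios, and which protected areas that shift newly
exposes. This vignette explains the model, its assumptions, every tunable
parameter that matters, what the bundled simulator does and does not
emulate, and the numerical choices made where the design was genuinely
open.

## Data model

All rasters live on one regular WGS84 lon/lat grid (`sdm_grid`): row 1 is
the northernmost band, cells are half-open `[edge, edge + cell_size)` in
both axes, and missing data is `NA`. Cell areas are spherical,

$$A(\text{row}) = R^2 \, \Delta\lambda \, (\sin\varphi_{top} - \sin\varphi_{bot}),
\qquad R = 6371.0088\ \text{km},$$

so a range's area is correct even though cells shrink poleward; tests can
inject unit cell areas to check the accounting arithmetic in isolation.
Rasters are read and written as ESRI ASCII grids (a plain-text,
north-up, square-cell format), occurrences as `species,lon,lat[,source]`
CSV, and protected areas as a GeoJSON FeatureCollection of polygons with
`id`, `name`, `protected_species` (semicolon-separated) and
`protected_ecosystem` properties.

## The modelling procedure

**Spatial filtering.** All records in one grid cell collapse to a single
occurrence (the first record in input order is the representative). This
is the usual guard against herbarium collection bias; with the default
analysis grid it corresponds to the common "one record per ~10–25 km cell"
rule. Filtering is idempotent and never invents points.

**Collinearity pruning.** Pearson correlations are computed over a seeded
random sample of at most `prune.max_cells` (default 10⁴) complete cells.
Variables are scanned in a user-supplied priority order — the package's
stand-in for the expert judgement of "keep the variable that is more
relevant and easier to interpret" — and a variable is kept iff its |r|
with every already-kept variable is ≤ `prune.threshold` (default 0.8).
Categorical layers (e.g. soil class) bypass the scan. The greedy scan is
order-dependent by design: the priority list *is* the relevance input.

**Pseudo-absences.** Presence-only data need background points. The
package uses envelope exclusion: a surface range envelope (below) is fit
to the presences, predicted over the grid, and `pa.n` cells are drawn
uniformly *without replacement* from the cells the envelope scores 0
(minus presence cells). Sampling without replacement avoids duplicated
rows; the paper-style alternative of fixed counts per species is available
through `pa.n`, while the default is a balanced design (`pa.n` = presence
count). The draw is repeated `pa.replicates` times (default 3) with
replicate seeds derived deterministically from the global seed, because a
single background draw is itself a noise source worth averaging over.

**Learners.** Two algorithms are native:

* *SRE* — the BIOCLIM-style surface range envelope. Per continuous
  variable it keeps the central `1 − 2q` interval of the presence values
  (linear-interpolation quantiles, default `q = 0.025` per side — the
  conventional envelope default, and configurable). A site scores 1 iff
  every variable lies inside its interval, bounds inclusive; inclusivity
  makes tie behaviour at quantile edges deterministic.
* *GLM* — logistic regression with optional quadratic terms (default
  degree 2, so unimodal responses are representable), categorical
  predictors one-hot encoded, fitted by IRLS to tolerance 1e-8 within 100
  iterations. If the fit walks to the boundary (non-convergence,
  near-zero deviance, or runaway coefficients — all symptoms of
  (quasi-)separation, which envelope-excluded background data makes
  quite likely), the model is refitted with an L2 penalty of 1e-6 on
  internally standardized features and a warning is raised.

Any further algorithm joins through `register_adapter()`, which runs the
candidate through a contract test (scores in [0, 1], deterministic
prediction, reproducible refit under a fixed seed) and refuses violators.
The ensemble machinery is deliberately agnostic to which learners are
enabled.

**Evaluation.** Each training set is split `evaluation.n_splits` times
(default 5) into stratified random 70/30 train/test parts. The source
tradition describes this design as "five-fold cross validation" while
operationally specifying random 70/30 splits; the two are incompatible,
and the package follows the operational description — five *independent*
stratified splits — with a true partitioning k-fold available via
`evaluation.mode = "kfold"`. Stratification guarantees both classes on
both sides even for small datasets. Each run is scored on the held-out
rows only: AUC in its rank (Mann–Whitney) form with ties counted ½, and
TSS at the threshold that maximizes it. Candidate thresholds are the
distinct score values under the rule `score ≥ t → presence`; among equally
optimal candidates the smallest is returned, a deterministic tie-break
that matters because near-separable data produce wide optimal plateaus.

**Ensemble.** For every (algorithm × pseudo-absence replicate)
combination, the mean TSS across split replicates is the skill summary.
Combinations with mean TSS > `ensemble.retention_tss_min` (default 0.7)
are refitted on their full training set — refitting uses all the
information for the final map, the standard behaviour of ensemble
platforms — and enter the ensemble weighted by that mean TSS (weights
normalized at prediction time). The plain envelope typically falls at or
below the retention bar on real data and is excluded by the same rule as
any other member. Continuous member scores are averaged; members are not
binarized before averaging.

**Binarization.** One threshold per species: the max-TSS cut-off of the
ensemble's scores on the pooled presence/pseudo-absence rows (all
replicates). It is fixed from the *baseline* scenario and reused for every
future projection — gain/loss accounting is meaningless if the
classification rule changes between periods.

**Range change and risk.** Under the full-dispersal assumption each
non-missing cell is classified loss (1→0), stable (1→1) or gain (0→1), so
`current = loss + stable` and `future = stable + gain` hold exactly, and

$$\text{net %} = \operatorname{round}\!\big(100 \cdot (\text{gain} - \text{loss}) / \text{current}\big),$$

rounded half away from zero to match the `+15 %` reporting convention. A
protected area is *newly exposed* under a scenario iff the current binary
range does not overlap it at all but the future one does; overlap means at
least one suitable cell whose **center** lies inside the polygon
(even–odd rule). Cell-center containment is deterministic and
resolution-consistent; fractional-cell weighting is out of scope. The risk
report counts threatened reserves, deduplicated protected plant species
and ecosystems across them, and total exposed area.

## The virtual-species simulator

Real studies of this kind rest on WorldClim-style climate normals, future
projections from GCM ensembles, herbarium occurrences and the world
protected-area database — inputs far too heavy to bundle, and with no
knowable "true range" to validate against. The simulator replaces them
with the smallest structures that preserve what the pipeline actually
consumes:

* **Landscape** — each predictor is a tilted plane (direction, slope,
  intercept) plus box-smoothed Gaussian noise; future scenarios add a
  constant per-layer delta *reusing the baseline noise field*, so the
  stated delta is the only difference between periods and the climate
  signal is isolated from noise regeneration.
* **Species** — a product-Gaussian niche
  $s(x) = \prod_v \exp(-(x_v - \mu_v)^2 / 2\sigma_v^2)$, maximal where
  every variable sits at its optimum; the *true range* is
  `s ≥ suitability_threshold`. Presence records are drawn by accepting
  uniformly-drawn cells with probability `s × detection_bias` — but only
  from occupied (true-range) cells, since a genuine record can only come
  from a site the species inhabits — and jittered uniformly within the
  cell.
* **Reserves** — non-overlapping axis-aligned rectangles with 0–3
  protected species and an ecosystem label from fixed vocabularies, so
  report aggregation is testable without real attribute tables.

The bundled `demo_study()` uses a 60 × 80 grid (0.25°) over 95–115°E,
20–35°N: annual mean temperature 28 °C at 20°N falling 0.7 °C per degree
of latitude (a realistic lapse for subtropical China), annual
precipitation rising 600→1400 mm west to east, and a deliberately
collinear temperature-seasonality layer that the pruning stage must drop.
The virtual invader's thermal optimum (μ = 30 °C, σ = 2.5) sits at the
warm edge of the landscape, so its realized range is warm-truncated — the
configuration of a tropical-origin invasive — and the +1 °C / +2 °C
scenarios expand the true range northward, giving an unambiguous positive
net change for sign-recovery tests. 300 presence records are drawn by
default.

**What the simulator does not emulate:** spatially structured sampling
bias, positional error in records, interactions between predictors,
dispersal limits, land use, and biotic interactions. Passing recovery
tests therefore show that the pipeline correctly recovers a clean,
climate-only niche signal — not that real projections at this skill level
are attainable, where all of the above degrade performance.

## Numerical choices and degenerate inputs

* Quantiles are linear-interpolation (type 7) throughout.
* A presence variable constant across records collapses its envelope
  bounds to that constant, with a warning rather than an error.
* Rows with any missing predictor get `NA` scores and are excluded from
  metrics; missing cells stay missing through projection, binarization
  and accounting.
* AUC/TSS raise errors (never silent NaN) when a class is absent or a
  confusion-matrix margin is zero.
* A single global seed fans out into per-stage streams (landscape noise,
  presence sampling, each pseudo-absence replicate, each split, each
  stochastic fit) via multiplicative 32-bit mixing, so replicates are
  independent yet every run replays bit-for-bit from its manifest.
* Problem sizes in the tests and acceptance script (60 × 80 grid, 300
  presences, 10 replicate studies) were chosen as the smallest
  configuration at which all design cells stay well populated; everything
  scales to larger grids through the same interfaces.

## Estimated versus true change

On the simulated study the binarized current range tracks the true range
closely (TSS ≈ 0.92–0.97 across seeds), but the *magnitude* of the net
range change is systematically smaller than the truth: the fitted range
is slightly wider than the true range at the envelope margins in both
periods, which inflates the `current` denominator and dampens the relative
change. The direction of change is recovered reliably, and only the
direction is asserted in the acceptance checks. This conservatism is worth
remembering when reading net-percent figures from real analyses of the
same design.

## Known limitations

Single outer polygon ring per reserve (no holes or multipolygons); no
reprojection or resampling (all inputs must share one grid); no
distance-weighted or target-group background schemes; no committee
averaging or per-scenario re-thresholding; geocoding of place-name-only
records is out of scope. The eight classical additional learners (GAM,
MARS, ANN, RF, GBM, Maxent, CTA, FDA) are not shipped natively — they are
a `register_adapter()` call away, and own their defaults.
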