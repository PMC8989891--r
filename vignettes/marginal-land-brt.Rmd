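---
title: "Boosted regression tree suitability modelling and marginal-land accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boosted regression tree suitability modelling and marginal-land accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Energy crops such as *Pistacia chinensis* (a biodiesel feedstock) are only
worth planting where the environment suits them **and** where cultivation
does not displace food production or intact ecosystems. A global
assessment therefore needs three pieces: a species distribution model
(SDM) relating occurrence records to environmental covariates; a map of
"marginal" land-use classes (savannas, shrublands, grasslands) on which
cultivation is considered acceptable; and area accounting that converts
masked raster cells into hectares, which finally feeds simple
biodiesel-volume and emissions-abatement arithmetic.

`marginalsdm` implements that whole chain, together with a synthetic-data
generator that stands in for the real inputs (WorldClim-style climate
layers, ISRIC-style soils, SRTM-style topography, a MODIS IGBP-style
land-cover map, GBIF-style occurrence downloads), so every stage is
testable offline and against a known truth.

## The model

### Design table

Occurrence records are aggregated to distinct presence cells on a common
geographic grid (0.05° by default, half-open cell intervals so each point
belongs to exactly one cell). Because true absences are unobserved,
background "pseudo-absence" cells are sampled uniformly, without
replacement and disjoint from the presences, from a *climatic envelope* of
cells the species is known not to tolerate: mean annual temperature below
5.8 °C or above 28.4 °C, **or** annual precipitation below 400 mm or above
1900 mm. The published description of this rule is grammatically ambiguous
between OR and AND across the two climate axes; OR is the default here
(each axis independently disqualifies a cell; AND would leave almost only
cold deserts) and `envelope_logic = "and"` is available. One absence is
drawn per presence, giving a balanced table.

### Boosted regression trees

The response is presence/absence $y \in \{0,1\}$ modelled on the log-odds
scale by an additive ensemble of shallow regression trees, fitted
stagewise against the Bernoulli deviance:

* initialise $F_0 = \log(\bar p / (1-\bar p))$;
* at stage $t$, compute $p_i = \operatorname{logit}^{-1}(F_{t-1}(x_i))$
  and fit a depth-limited regression tree to the pointwise gradient
  $z_i = y_i - p_i$ on a `bag_fraction` subsample (without replacement);
* each terminal node gets one Newton step
  $\gamma = \sum z_i / \sum p_i(1-p_i)$ over its bagged rows;
* $F_t = F_{t-1} + \nu\,\gamma_{\text{leaf}(x)}$ with learning rate $\nu$.

Splits are found by exhaustive variance-reduction search over observed
thresholds; categorical predictors (soil class) are split by ordering
levels by their mean gradient, which finds the optimal level subset for
squared error without exponential search. Each split records its
squared-error improvement; **relative contribution** of a covariate is the
sum of improvements over all splits using it, normalised to 100%.
**Partial dependence** sweeps one covariate over a grid with the others
held at their training means (modes for categoricals), the convention used
in the suitability-modelling literature; averaging over training rows is
available as an alternative mode.

The number of trees is the one free parameter that matters most. It is
chosen as in the `gbm.step` tradition: label-stratified ten-fold
cross-validation, growing every fold in increments of `step_size` (50)
trees, tracking mean held-out deviance, stopping after `patience` (5)
checkpoints without improvement, and selecting the checkpoint with minimal
held-out deviance. Discrimination is summarised by the ROC AUC in its
Mann–Whitney form (exact, midranks for ties).

Defaults (`learning_rate = 0.01`, `tree_complexity = 5`,
`bag_fraction = 0.75`) are the conventional choices in this literature;
the source assessment does not state its values, so these are defaults,
not claims. The analysis scripts and acceptance runs use faster settings
(rate 0.05–0.1, depth 2–3, ≤ 150–300 trees) appropriate for their smaller
synthetic problems; these sizes are stated below.

### Ensemble and uncertainty

Thirty members are fitted, each on an independent label-stratified 50%
train split with per-member CV tree selection, each predicting suitability
over the full raster stack. The pixel-wise mean is the suitability map;
the pixel-wise **population** standard deviation (denominator $n$, since
the ensemble is the entire population of fitted members) is the
uncertainty map. "Bootstrapped" in this tradition can mean either
re-splitting or resampling rows with replacement; re-splitting is the
default and `with_replacement = TRUE` gives the other reading. Train and
test AUC are reported as mean ± SD over members. Raster prediction is
chunked by rows purely to bound memory; the output is independent of the
chunking.

### Marginal land and areas

The mean map is thresholded at 0.5 (inclusive: a cell exactly at the
threshold is suitable — the tie rule is configurable), then intersected
with the allowed land-use classes. "Shrublands" is expanded to both the
closed and the open shrubland classes, giving the five-class marginal set:
woody savannas, savannas, closed shrublands, open shrublands, grasslands.

Cell areas are latitude-corrected on the sphere:
$A = R^2\,\Delta\lambda\,(\sin\varphi_N - \sin\varphi_S)$ with
$R = 6371.0088$ km, so summing a global grid reproduces $4\pi R^2$ to
floating-point accuracy. Because the source assessment never states its
accounting method, a `flat_count` mode (2500 ha per 0.05° cell, the
"5 × 5 km cell" reading) is also provided. Areas are cross-tabulated by
zone × class with composition percentages; zones are supplied as an
integer raster (no political borders ship with the package).

### Scenario arithmetic

Biodiesel volume = area × utilization × per-hectare yield;
abatement = volume × per-litre factor (low bounds multiplied together,
high bounds together); goal share = abatement / 28 GtCO₂e × 100.
The literature coefficients behind the published ranges are not printed
anywhere accessible, so the shipped defaults are *back-calculated* from
the published 30%-utilization scenario over 1311.85 Mha
(≈ 954.2 and ≈ 1695.6 L ha⁻¹ yr⁻¹; ≈ 0.719 and ≈ 2.922 kg CO₂e L⁻¹) and
are labelled as derived, not sourced. Results are exact internally and
rounded (half-even) to two decimals only at formatting time. Note one
consequence of published rounding: rescaling the printed 30% upper bound
(667.31 BL) to 50% gives 1112.18 BL where 1112.19 was printed from
unrounded intermediates.

## The synthetic study system

Continuous covariates are Gaussian-smoothed white noise (σ in cells,
per layer) affinely rescaled into realistic ranges; temperature blends in
a monotone north–south gradient (normalised cosine of latitude) so the
climatic envelope partitions the map spatially; soil class and land use
are rank-transformed smoothed fields cut at class probabilities, which
yields clumped patches whose empirical fractions match the requested
probabilities; a border "ocean" is NoData everywhere. The default grid is
400 × 240 cells at 0.05° spanning 20° of latitude, so spherical cell areas
vary materially; the default occurrence draw is 1923 records sampled with
replacement (so they deduplicate to fewer presence cells, as real GBIF
records do: the real assessment's 1923 records collapsed to 670 cells).

The true suitability surface is logistic in the standardized covariates
with defaults mirroring the published importance ordering (water vapour
pressure strongest, then temperature) **plus negative quadratic terms on
temperature and precipitation**. The quadratic niche matters: it makes
suitability collapse toward the climatic extremes, which is exactly what
the pseudo-absence envelope assumes about the species. With a purely
linear truth a substantial share of presences falls inside the envelope
background and no model can separate the classes (test AUC plateaus near
0.87 regardless of capacity); with the niche-shaped truth the ensemble
reaches test AUC ≥ 0.95 on the default system.

What the generator does **not** emulate: the marginal distributions and
cross-correlations of real climate layers, sampling bias of real
occurrence records, coastline geometry, or political borders. Passing
tests therefore demonstrate the correctness and statistical behaviour of
the machinery, not the real-world map.

### The effect-recovery experiment

The generator's reason to exist is that planted effects should be
recoverable: fitting the pipeline on data with known weights should rank
relative contributions accordingly. One subtlety is documented here
deliberately: envelope-based pseudo-absences make the labels a partly
deterministic function of temperature and precipitation, so those two
covariates carry genuine signal *regardless of the planted weights* — with
envelope absences, "recovering the planted ranking" is ill-posed. The
recovery experiment therefore samples its background uniformly from all
valid cells (same sampling machinery, neutral mask) and plants
vapr = 3.0 (strong), srad = 1.5 (weak), all else 0, on σ = 3 fields,
300 presences on a 100 × 100 grid, fitted with depth-2 trees, rate 0.05,
150 trees. Under that design the expected ordering
RC(vapr) > RC(srad) > max(noise) holds in ≥ 28 of 30 seeded replicates
(30/30 at the frozen defaults). The ensemble-AUC check, by contrast, runs
the full envelope pipeline.

## Numerical choices and edge cases

* **Tie-breaks.** Equal-gain splits prefer the alphabetically-first
  variable name, then the lowest threshold. Name rank rather than column
  index keeps relative influence invariant to the column order of the
  design table (identical partitions induced by two smooth covariates do
  occur in practice); both rules are equally deterministic.
* **Thresholds** between observed values are midpoints; routing is
  `x < threshold` to the left child.
* **Unseen categorical levels** at prediction time route to the child
  with more training weight.
* **NoData** is NA internally, a sentinel only in files; it propagates
  through every raster operation, is never eligible as background, and
  rows containing it are dropped (with counts) before modelling.
* **Degenerate inputs** fail loudly: single-class labels, all-zero
  suitability, infeasible envelopes (< 1% eligible cells), mismatched
  grids, empty grids in partial dependence, n_models < 2 (ensemble SD
  undefined). An empty marginal raster tabulates to zeros with a warning
  rather than NaN percentages.
* **Seeds.** One master seed drives everything; stage seeds are derived
  by fixed documented offsets, member seeds as `seed + 7919·m`. Two runs
  from one seed produce identical manifests.

## Problem sizes

Unit tests use 80 × 120 to 100 × 200 grids at 0.2–0.25° with 150–400
presences and ≤ 200 trees; the acceptance run uses an 80 × 120 system with
400 presences for the 30-member ensemble and thirty 100 × 100 replicates
for effect recovery; the analysis scripts run the full default 400 × 240
system. These sizes were chosen so each stage completes in seconds to a
couple of minutes on one CPU while leaving the statistical properties
(envelope feasibility, recovery, discrimination) comfortably measurable.

## Known limitations

* The BRT core supports Bernoulli loss only — no Poisson/multinomial, no
  monotonicity constraints, no interaction-strength statistics.
* Categorical predictors are limited to 31 levels (bitmask splits).
* Raster I/O is the plain-text ESRI ASCII grid; there is no GeoTIFF
  reader/writer, and no reprojection — all layers must share one
  geographic grid.
* The scenario coefficients are back-derived placeholders, not a
  literature review; any serious application should supply its own yield
  and abatement factors.
* Real-data artefacts (sampling bias, spatial sorting bias in AUC,
  coordinate errors) are out of scope; results on synthetic data bound
  what the machinery can do, not what real data will give.
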