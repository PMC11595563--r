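---
title: "Methods: ensemble distribution models, divergence times and the spatiotemporal pattern"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble distribution models, divergence times and the spatiotemporal pattern}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylospat)
```

## The scientific question

Where a taxon can live today and when its lineages diverged are usually
studied separately. `phylospat` joins the two: it estimates a habitat
suitability surface for a taxon from occurrence records and environmental
layers, maps the mean divergence time (MDT) of the species found in each
grid cell of the study area, and asks whether cells in more suitable
habitat harbour older lineages — the signature expected when a group
originated and first diversified in its most favourable region and only
later dispersed into marginal habitat. The motivating use case is a
parasitic macrofungal genus in China whose highly suitable habitat
concentrates in the southeast, but every stage is generic.

## Pipeline overview

1. **Occurrence preparation.** Records within 10 km of one another are
   treated as replicates and collapsed to one (greedy scan in input order;
   haversine distance on a 6371.0088 km sphere in geographic mode,
   Euclidean km in planar mode). Environmental layers with pairwise
   Pearson |r| > 0.8 (computed over all jointly valid raster cells) are
   reduced to one representative per correlated group.
2. **Ensemble distribution model.** 500 pseudo-absence points are drawn
   uniformly from valid, unoccupied cells; the draw is repeated 3 times.
   Four learner families — logistic GLM, GAM with smooth terms, gradient
   boosting (2500 trees, depth 3, shrinkage 0.01) and random forest (500
   trees) — are each fitted on 10 random 75/25 calibration/evaluation
   splits per pseudo-absence set, giving 4 x 3 x 10 = 120 member models.
   Members are scored by AUC and by the TSS at the threshold that
   maximises TSS on their held-out split. Two ensembles are projected:
   Committee Averaging (the fraction of members voting presence at their
   own thresholds) and the AUC-Weighted Mean of continuous member scores.
3. **Suitability classes.** The ensemble map is split into 4 levels with
   exact Fisher–Jenks natural breaks (dynamic program minimising total
   within-class sum of squared deviations; classes use half-open
   `(lower, upper]` intervals).
4. **Divergence times.** Species divergence time is represented by stem
   age — the age of the node where the species' terminal branch (or, for
   species with several collections on the tree, the parent of their MRCA)
   attaches. Ages are measured backwards from tips at 0.
5. **Ancestral areas.** Tip areas (four quadrants) evolve under an Mk
   model; ER, SYM and ARD parameterisations are fitted by maximum
   likelihood via Felsenstein pruning, compared by AIC (or raw
   likelihood), and per-node marginal state probabilities are computed
   under a uniform root prior.
6. **Spatiotemporal pattern.** A 100 km grid is laid over the occurrences;
   each occupied cell's MDT is the mean stem age of its (deduplicated)
   species set. Cells are grouped by the suitability class of their mean
   ensemble suitability, and group MDTs are compared with a tie-corrected
   Kruskal–Wallis test followed by Dunn's pairwise z tests with Holm
   adjustment.

## The synthetic data generator

All stages are testable without downloads because the package generates
its own inputs with known ground truth:

- **Environmental layers** are mixtures of eight low-frequency cosine
  waves with random orientation and phase, standardised per layer — smooth
  and spatially autocorrelated like interpolated climate surfaces, but
  without any seasonal semantics. Declared collinear pairs are rebuilt as
  `r * layer_i + sqrt(1 - r^2) * e` with `e` made empirically orthogonal
  to `layer_i`, so the achieved sample correlation equals the target
  exactly.
- **True suitability** is `logistic(intercept + sum(coef * layer))` with
  coefficients chosen by the scenario, giving an exact recovery target for
  the ensemble.
- **Presences** are cells drawn with probability proportional to
  suitability, one record per draw at the cell centre.
- **Chronograms** are Yule trees built constructively (exponential
  waiting times with rate `birth_rate * k`, uniform choice of the
  splitting lineage, a final waiting time so terminal branches are
  positive), then rescaled to a fixed root age in Myr.
- **Tip areas** evolve root-to-tips under an equal-rates Mk chain using
  the closed-form transition probabilities, optionally from a fixed root
  state.

Geometry is planar km, so distances are exact and no projection enters the
tests; the real-data path uses WGS84 coordinates with haversine distances,
and 100 km gridding of real data should be done on an equal-area
projection supplied by the user.

### The benchmark scenario

`paperlike_scenario()` fixes the study conditions used by the tests and
the acceptance script: a 1000 x 1000 km area at 20 km resolution (2500
cells), five environmental layers with one deliberately collinear pair
(target r = 0.9), a suitability surface anchored in the south-east
quadrant through a linear trend on the active layer (coefficients
`env3 = 2.5`, `env4 = 0.8`, intercept −1.5), 150 presence records, a
40-tip Yule chronogram (speciation rate 0.05/Myr) rescaled to an 80 Myr
root, and quadrant tip areas simulated from a south-east root at
0.005 transitions/Myr — roughly one expected dispersal event per
root-to-tip path, i.e. dispersal late and rare relative to the root age.
The oldest third of species (by stem age) is constrained to records in the
south-east quadrant, planting exactly the pattern the pipeline is meant to
detect: the top suitability class should show the highest mean MDT, with
a significant Kruskal–Wallis test. These values were chosen once, as
plausible analogues of a regional fungal radiation, and are the fixed
conditions under which the package's recovery claims hold.

What the generator does **not** emulate: climate seasonality and
inter-layer physical constraints, spatially biased sampling effort,
georeferencing error, taxonomic uncertainty, and non-ultrametric trees.
Passing tests therefore demonstrate the machinery is correct and that the
pattern is recoverable under honest conditions — not that any real dataset
will show it.

## Numerical and design choices

- **Thinning** is a greedy first-come scan: deterministic and stable,
  with an optional seed to randomise scan order for sensitivity probes.
  Whether the 10 km rule pools species or applies per species is
  configurable; the default pools all records.
- **Collinearity retention** is deterministic input-order priority by
  default ("random retention" is available behind a seed); the kept set
  never contains a pair above the threshold, which is asserted on every
  run.
- **Member binarisation for CA** uses each member's own max-TSS threshold
  on its evaluation split, the convention of ensemble SDM platforms.
  Candidate thresholds are midpoints of consecutive unique scores, ties
  broken toward the lower threshold.
- **WM weights** are proportional to member AUC over all members; no QC
  filtering is applied before ensembling by default (members with
  AUC > 0.8 and TSS >= 0.7 are only *flagged*), matching the practice of
  mixing the full model grid. `qc_filter = TRUE` restricts to flagged
  members.
- **Ensemble evaluation** uses the pooled presences and pseudo-absences;
  member statistics are reported as mean ± sd across the grid.
- **AUC ties** count one half (Mann–Whitney), stated explicitly because
  tree-based learners emit tied scores.
- **Gradient boosting** is implemented with `xgboost` (binary logistic
  objective) under the documented defaults above; all hyperparameters are
  exposed through the `hyper` argument.
- **Jenks breaks** are the class maxima of the lower classes, the usual
  convention for natural-breaks software; the dynamic program is exact, so
  it agrees with exhaustive enumeration wherever enumeration is feasible.
- **Mk numerics**: ER transition probabilities use the closed form
  `P(stay) = 1/k + (k-1)/k exp(-kqt)`; SYM/ARD use one eigendecomposition
  of Q per likelihood evaluation, with a scaling-and-squaring fallback for
  defective generators. Rates are optimised on the log scale in
  `[1e-8, 1e3]`/Myr from three fixed starts scaled to tree height. The
  root prior is uniform. Fewer than two observed states puts the rate MLE
  at the lower bound, with a warning rather than an error.
- **Outgroups**: reconstruction is intended for the ingroup; prune
  outgroup tips before fitting, or encode genuinely uncertain tips as
  ambiguity sets (`"SE|SW"`), which sum the likelihood over member states.
- **Kruskal–Wallis** uses the tie-corrected H with a chi-square reference;
  an exact permutation p-value (full enumeration up to a budget, Monte
  Carlo beyond it) is available for small cell counts. The post hoc
  procedure is Dunn's z on pooled ranks with Holm adjustment — the
  conventional pairing, since rank-based post hoc methods are rarely named
  in applied reports.
- **Grid cells** are half-open and lower-left inclusive; a record on a
  boundary belongs to the cell above/right of it in coordinate order.
  Points exactly on a dividing line are assigned to the east/south side.
- **Seeds**: one master seed expands into per-stage seeds through a
  multiplicative hash chain (`derive_seeds()`), so any stage can be rerun
  independently and reruns are bit-identical.

## Problem sizes used by the tests

The bundled checks run at deliberately modest sizes: enumeration oracles
up to 12 values / 4 classes (Jenks), 6 tips / 4 states (Mk), total n = 8
(Kruskal–Wallis); rate recovery on a 200-tip tree; the full 120-member
grid on the 2500-cell benchmark raster (boosting shortened to 500 trees
there); and 20 pipeline replicates with a reduced member grid (GLM + RF,
2 pseudo-absence sets, 2 CV runs) for the detection-power check. These
sizes keep the whole suite comfortably reproducible on a laptop while
exercising every code path at full fidelity.

## Known limitations

- The member grid is fitted presence vs pseudo-absence; prevalence is
  therefore artificial and the ensemble map is a relative suitability
  index, not an occupancy probability.
- Variable importance is the permutation kind (1 − |r| between original
  and permuted-predictor predictions); correlated predictors share credit,
  which is one reason the collinearity filter runs first.
- The Mk reconstruction assumes the chronogram is correct and ignores
  dating uncertainty; ranges spanning several areas are handled as
  ambiguity sets, not as polymorphisms with their own dynamics.
- Real-data gridding requires the user to supply equal-area projected
  coordinates; the package does not reproject.
```
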