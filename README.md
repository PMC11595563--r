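# phylospat

Spatiotemporal pattern analysis for a taxon: where can it live, and are
its older lineages concentrated in its best habitat?

`phylospat` joins two analyses that are usually run separately:

1. **Ensemble species distribution modelling.** Occurrence records are
   spatially thinned (records within 10 km are replicates), collinear
   environmental layers are removed (pairwise Pearson |r| > 0.8), and a
   grid of member models — GLM, GAM, gradient boosting and random forest,
   each fitted to 3 replicate sets of 500 uniform pseudo-absences under 10
   random 75/25 calibration/evaluation splits (4 × 3 × 10 = 120 members) —
   is combined by **Committee Averaging** (fraction of members voting
   presence at their own max-TSS thresholds) and by the **AUC-Weighted
   Mean** of member scores. The ensemble map is split into four levels by
   exact Fisher–Jenks natural breaks.
2. **Divergence-time mapping.** From a time-calibrated ultrametric tree,
   each species' divergence time is its **stem age** (the age of the node
   its terminal branch attaches to). A 100 km grid is laid over the
   occurrences; every occupied cell gets the **mean divergence time
   (MDT)** of its species set. Ancestral areas are reconstructed with
   ER/SYM/ARD **Mk models** (Felsenstein pruning, ML rates, marginal node
   probabilities). Finally, cell MDTs are grouped by habitat-suitability
   class and compared with a tie-corrected **Kruskal–Wallis** test and
   Dunn–Holm post hoc pairs — the qualitative signature of a taxon that
   originated in its most suitable region is the top class holding the
   highest MDT.

A synthetic-data module generates every input with known ground truth —
smooth autocorrelated raster stacks with controlled collinearity,
presences from a known logistic suitability surface, Yule chronograms and
Mk-evolved tip areas — so the whole pipeline is testable offline.

Key quantities, in the field's notation: AUC = P(score(presence) >
score(absence)) with ties ½; TSS = sensitivity + specificity − 1;
CA(x) = (1/M) Σ 1[sᵢ(x) ≥ τᵢ]; WM(x) = Σ wᵢ sᵢ(x) / Σ wᵢ with wᵢ = AUCᵢ;
Mk: P(t) = exp(Qt) on k areas with uniform root prior; MDT(cell) = mean
stem age of the species present.

## Worked example

The bundled benchmark scenario plants a known pattern: suitability is
anchored in the south-east quadrant and the oldest third of species (by
stem age on an 80 Myr, 40-tip chronogram) only occurs there. A reduced
model grid is enough to recover it:

```r
library(phylospat)

res <- run_pipeline(list(
  seed = 3,
  algorithms = c("GLM", "RF"), cv_runs = 2,
  n_pseudo_absences = 200, n_pa_sets = 2,
  hyper = list(rf_trees = 200)
))

res$fit
#> <sdm_ensemble> 8 member models (8 usable): GLM/RF x 2 PA sets x 2 CV runs
#>   member AUC 0.764 +/- 0.050, TSS 0.460 +/- 0.075, 0 pass QC

res$kw
#> Kruskal-Wallis: H = 21.5244, df = 3, p = 8.192e-05 (n = 4/11/22/17)

round(tapply(res$cells$mdt, res$cells$suitability_class, mean), 2)
#>     1     2     3     4
#>  6.53  9.55  8.89 17.27

res$manifest$selected_ancestral_model
#> [1] "ER"
```

Reading this: the 54 occupied 100 km cells fall into four suitability
classes (class 4 = most suitable); the most suitable class has by far the
highest mean divergence time (17.3 Myr vs 6.5–9.6 Myr), the Kruskal–Wallis
test confirms the MDT differences (p ≈ 8 × 10⁻⁵), and the equal-rates Mk
model is selected by AIC for the tip areas — together, the planted
"old lineages in the best habitat" pattern is recovered. `res$posthoc`
lists which class pairs differ (Dunn z, Holm-adjusted p), and
`res$wm_map` / `res$classification` hold the continuous and classified
suitability maps.

On real data, point `config$paths` at an occurrence CSV
(`species,lat,lon`), a directory of ESRI ASCII grids, a Newick chronogram
and a tip-area TSV, and set `mode = "real"`; coordinates should be
equal-area projected km for the 100 km gridding.

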