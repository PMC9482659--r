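# endemicshift

An R package and analysis workflow for projecting climate-change impacts on
endemic species with ensemble species distribution models (SDMs), on a fully
synthetic study system with known ground truth.

## The problem

Climate projections that include a large-scale singular event — a rapid
ice-sheet melt weakening the Atlantic overturning circulation — can be *more
climatically dissimilar* from the present than a plain high-emission pathway
even while mean warming is weaker. For species endemic to a single country,
that dissimilarity translates into shrinking climatically suitable ranges,
falling species richness and turnover in community composition.
Quantifying that chain (occurrences → niche models → binary range maps →
stacked biodiversity metrics) involves many interacting filtering rules,
thresholds and consensus conventions. This package implements the full chain
at desk scale and validates every link against virtual species whose true
niches and ranges are known by construction, contrasting a **control**
warming family with a strictly more dissimilar **melting** family at three
horizons (T1–T3).

## The method

For each species with ≥ 25 unique occurrence cells (capped at 500,
endemicity checked against a buffered country mask):

* **Accessible area** M = (4° buffer around occurrences) ∩ (occupied
  ecoregions); projections use M dilated by 2° (full dispersal inside).
* **Predictors**: the 19 bioclim-like layers screened per species to
  pairwise |r| < 0.8, dropping the higher-VIF member of the worst pair.
* **Training data**: up to 10,000 pseudo-absences sampled in M, weighted to
  prevalence 0.5; 10 stratified 70/30 train/test replicates.
* **Algorithms** (one fit/predict contract): surface range envelope,
  ridge-penalized logistic with quadratic features, classification tree,
  probability random forest, and a Gaussian density-ratio model.
* **Ensemble**: members with held-out AUC > 0.7 are combined by AUC-weighted
  mean; the pooled held-out max-TSS threshold (TSS = sensitivity +
  specificity − 1) binarizes the consensus map and is frozen for all future
  projections.
* **Metrics**: per-species range change ΔA/A with five change categories and
  complete-loss flags; presence–absence matrices; species richness SR and
  ΔSR = SR_future − SR_present; potential species hotspots
  (SR > 0.6 · maxSR per country, frozen present-day cutoff); per-pixel
  temporal Sørensen dissimilarity β_SØR = (b + c)/(2a + b + c) within
  hotspots; cross-algorithm coefficient of variation; and climate profiles
  of scenario deltas and of richness-gain vs richness-loss areas.

## Worked example

The numbered scripts under `analysis/` run the whole study
(60 × 60 grid, 12 countries, 30 virtual species, 5 algorithms × 10
replicates, 2 scenario families × 3 horizons):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_prepare.R
Rscript analysis/03_fit_ensembles.R
Rscript analysis/04_project_metrics.R
Rscript analysis/05_climate_profiles.R
```

Representative output (seed 1):

```
T3: standardized climate distance control 2.166 < melting 4.866
30/30 species retained (reasons: none=30)
modeled 30 species; member AUC median 0.910; ensemble AUC median 0.985
median range change (%) and complete-loss share (%):
  control  T3:  -12.7%  loss   0.0%
  melting  T3:  -29.0%  loss  26.7%
median temporal beta_SOR within PSH:
  control  T3: 0.200
  melting  T3: 0.250
```

Reading this: the melting family is built to be ~2.2× more climatically
dissimilar from baseline than the control at every horizon; the ensembles
recover the known niches well (median consensus AUC 0.985); and the
dissimilarity ordering propagates through every downstream metric — median
range loss, complete range loss and hotspot composition turnover are all
worse under melting than under control at each horizon, the qualitative
tipping-point pattern the pipeline is designed to expose. Tables land in
`results/` (`range_change.csv`, `psh_extent.csv`, `bsor.csv`, ...).

A single call does the same in-process:

```r
library(endemicshift)
run <- run_pipeline(default_config(seed = 1))
run$summary$range_change_summary
```

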