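---
title: "Methods: ensemble niche models and biodiversity metrics on a synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble niche models and biodiversity metrics on a synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`endemicshift` implements a complete ensemble species-distribution-modeling
(SDM) pipeline — occurrence filtering, accessible-area construction,
presence/pseudo-absence ensembles, TSS-threshold binarization, and stacked
biodiversity metrics — together with a synthetic-data module that generates
the world the pipeline runs on. The synthetic world is not a fixture: it is
the package's instrument for validation. Because every virtual species has
a known Gaussian niche and a known true range, the pipeline's output can be
scored against truth, which is impossible with real occurrence data.

The scientific question the default configuration encodes is a contrast
between two future-climate families: a **control** family (plain strong
warming) and a **melting** family that represents warming plus a
freshwater-forced weakening of ocean heat transport. The melting family is
*constructed* to be strictly more climatically dissimilar from the baseline
than the control at every horizon, even though its mean warming is smaller
— dissimilarity, not mean warming, is the stressor. The pipeline then asks
whether that ordering propagates through every downstream biodiversity
metric.

# The synthetic world

**Climate.** Each of the 19 bioclim-like layers is a Gaussian random field:
white noise convolved with a separable Gaussian kernel of standard
deviation `autocorr_length` cells (default 4), standardized, then mixed
with a single shared latent field with weights $\sqrt{\rho}$ and
$\sqrt{1-\rho}$ so that any two layers correlate at about
$\rho$ = `cross_corr` (default 0.6). Realistic collinearity matters because
the predictor-screening step must have genuine work to do. Layers are
placed on plausible bioclim scales (°C, mm); this is cosmetic since all
modeling re-standardizes.

**Countries and ecoregions.** The grid is partitioned into 12 contiguous
countries by nearest-seed (Voronoi) growth, each subdivided into 3
ecoregions the same way. Ecoregion ids are globally unique and nest within
countries. All cells are land by default; an ocean would only complicate
the small worlds used for testing without exercising any additional code
path.

**Virtual species.** A species is endemic to one country and has a
bell-shaped niche over 2–3 randomly chosen layers in globally standardized
climate space:
$$S(x) = \exp\left(-\sum_v \frac{(z_v(x)-\mu_v)^2}{2\sigma_v^2}\right),$$
with optima $\mu$ anchored at the standardized climate of a random cell of
its country (so maximum suitability 1 is attainable), breadths
$\sigma \in [0.6, 1.2]$ and occupancy threshold $\tau \in [0.3, 0.6]$. The
true range is the set of country cells with $S \ge \tau$. Draws are
rejected and retried unless the range has at least `min_range_cells`
(default 40 in the study configuration, shrunk automatically for small
countries) and at most `max_range_frac` (default 0.8) of the country's
cells. The upper bound encodes a biological expectation — an endemic
occupying its entire country is not a meaningful niche signal — and has a
practical corollary: it guarantees a non-empty pseudo-absence pool for
every species.

**Occurrences.** Records are drawn from the true range with probability
proportional to suitability (300 per species by default), placed at cell
centres. A `detection_noise` probability displaces a record uniformly
within the country; the study configuration uses 0 so that recovery tests
measure the pipeline, not the noise model. There is deliberately no
spatial sampling-bias model.

**Scenarios.** Each family is a named vector of per-layer drifts in
baseline-standard-deviation units, reached linearly at T3 (horizon $k$
applies $k/3$ of the full drift). Defaults: control
(bio01 +1.5σ, bio05 +1.2σ, bio12 −0.8σ, bio14 −0.6σ); melting
(bio01 +1.0σ, bio04 +1.2σ, bio05 +3.0σ, bio12 −1.8σ, bio14 −3.0σ). The
mean per-cell Euclidean distance to baseline in standardized layer space is
validated as a postcondition to be strictly larger for melting at every
horizon; generation fails loudly otherwise. Drift is spatially uniform, so
a +1σ drift on one layer yields a standardized distance of exactly 1 — a
property the tests exploit.

# What the generator does and does not emulate

It emulates: collinear, spatially autocorrelated climate; nested
political/ecological masks; endemism; suitability-biased sampling;
monotonically accumulating scenario change with a controlled dissimilarity
ordering. It does not emulate: coastlines and sea-level rise, dispersal
barriers beyond the projected-M clip, spatial sampling bias, taxonomic
error, land-use change, or any actual ocean-atmosphere physics. Passing
tests therefore demonstrate that the *pipeline machinery* is correct and
that its qualitative scenario contrast follows from climatic dissimilarity;
they say nothing about the magnitude of impacts on real species.

# Data preparation

Records snap to cells and deduplicate; a species needs ≥ 25 unique cells
(`min_records`) and is capped at 500 (`max_records`) by uniform subsampling.
Endemicity requires all cells to fall within one country dilated by
0.08333° (converted to whole cells by ceiling — conservative inclusion; one
cell at 0.5° resolution).

Predictor screening runs per species on its calibration cells: while any
kept pair has $|r| \ge 0.8$, the worst pair loses its member with the
higher variance inflation factor (VIF $= 1/(1-R^2)$ from an OLS regression
on the other kept layers); VIF ties drop the later layer in input order.
Running the screen per species on M (rather than globally) follows the
principle that collinearity structure is region-specific; the choice is
configurable in spirit since any cell set can be passed.

# Niche models and ensembles

The accessible area M is the intersection of a 4° occurrence buffer
(Chebyshev cell dilation) with the occupied ecoregions; if
$|M| \le |P| + 1$ (insular/degenerate cases) M falls back to the whole
country. Projections use M dilated by 2°, clipped to land — the
full-dispersal area.

Up to 10,000 pseudo-absences are sampled uniformly from M minus the
presence cells (never coinciding with presences, avoiding label conflict),
and weighted so total presence weight equals total absence weight
(prevalence 0.5). Ten stratified 70/30 splits keep prevalence stable across
replicates; a degenerate split (< 2 records in any stratum) is an error,
and `fraction = 1` is rejected because an empty test set cannot evaluate.

Five algorithm families share one fit/predict contract and standardize
predictors with frozen training means/sds (re-applied when projecting onto
future climates):

* **sre** — surface range envelope: the (2.5, 97.5) percentile box of
  presence climate; 1 inside, 0 outside. Monotone by construction: widening
  the window never shrinks the predicted range.
* **glm** — ridge-penalized logistic regression (fixed λ = 0.01) on linear
  + squared features; the quadratic terms give smooth unimodal responses.
* **cta** — a depth-capped regression tree on the 0/1 response.
* **rf** — a 100-tree probability random forest (bagged trees with feature
  subsampling), seeded and single-threaded for determinism.
* **maxlike** — a Gaussian density-ratio model: shrinkage-regularized
  Gaussians fitted to presence and background climates; the log ratio (an
  exponential-family model with linear + quadratic features) is mapped
  through the logistic function. Closed-form and deterministic.

Five distinct families preserve ensemble heterogeneity at desk scale;
the consensus machinery is roster-agnostic.

**Evaluation.** AUC is pairwise concordance with ties counted ½ (computed
via midranks, verified against a brute-force pair enumeration). TSS is
maximized over the fixed grid 0.00–1.00 in steps of 0.01, scoring a cell
present when suitability ≥ threshold; ties take the lowest threshold. Both
rules are frozen so that thresholds are exactly reproducible.

**Consensus.** Members with held-out AUC strictly above 0.7 join the
ensemble, weighted by their AUC (the conventional score-weighting default).
The ensemble is evaluated by pooling all members' held-out test cells
against the consensus scores — this yields a single TSS threshold per
species, which binarizes the present-day map and is *reused unchanged* for
every future projection (re-thresholding on future data is impossible
without future truth). A species with no passing member is flagged
unmodelable and excluded downstream with a logged reason rather than
aborting the run. Variable contributions are permutation importances (mean
AUC drop over 5 seeded permutations), computed once per algorithm on its
first passing member to bound cost; the top two variables are reported.

**Agreement.** The coefficient of variation is computed per cell across
algorithm-level consensus maps (sample sd / mean, cells with mean < 10⁻⁶
treated as no-data). Because the projected M contains many cells of
near-zero consensus suitability, the mean CV is dominated by those
low-suitability cells and is naturally much larger than the CV of
high-suitability cores.

# Biodiversity metrics

Range change is $\delta = (A_{fut}-A_{now})/A_{now}$ over binary-map cell
counts, with complete loss at $\delta = -1$, classified into five
configurable categories closed on the loss side: complete loss (−1),
severe loss (−1, −0.5], moderate loss (−0.5, 0), stable/gain [0, 0.5],
strong gain (> 0.5). The bins are a reporting convention, not a model
quantity.

Presence–absence matrices stack the binary maps; richness is the column
sum (the conservation identity $\sum_{cells} SR = \sum_{species} |range|$
is asserted exactly in tests). ΔSR is future minus present, so positive
values are gains — the convention that makes "gain areas" read naturally in
the climate profiles. Richness is standardized to [0, 1] within each
country for mapping.

Potential species hotspots are cells with SR strictly above
0.6 × present-day maxSR per country (0.2 and 0.9 as sensitivity settings).
The cutoff *value* is frozen from the present day and applied to future SR
maps: re-deriving maxSR from future maps would conflate shrinking richness
with threshold drift. Hotspot extent is reported relative to the
present-day extent; countries with zero modeled richness define no hotspot
(an error when requested directly, silently excluded by the pipeline).

Temporal Sørensen dissimilarity is computed per cell between the two
periods: with $a$ shared, $b$ present-only and $c$ future-only species,
$\beta_{SOR} = (b+c)/(2a+b+c)$; cells empty in both periods are no-data
(0/0). Medians are reported over all hotspot cells pooled and per country.

Climate profiles summarize (mean, quartiles with linear interpolation,
type 7) the per-cell scenario deltas of four annual-trend/extreme layers,
and the present-day climate of richness-gain vs richness-loss areas — cells
with ΔSR strictly above Q3 / below Q1 of the ΔSR distribution over its
valid support (cells with at least one species in either period; zeros
inside the support count toward the quartiles). A degenerate distribution
(Q1 = Q3, common under mild scenarios where most cells are unchanged) is an
error for the direct call and skipped with a note by the pipeline. The two
four-variable lists differ on purpose: scenario deltas use annual mean
temperature, annual precipitation, max temperature of warmest month and
precipitation of driest month (the layers that separate the families);
gain/loss profiles use annual trends plus the two seasonality layers.

# Determinism and problem sizes

A single top-level seed fans out to every stochastic step through a
31-bit string hash of (seed, stage/species/algorithm/replicate labels), so
adding species or stages never perturbs existing sub-seeds, and two runs of
the same configuration are bit-identical — including CSV outputs, which the
test suite checks byte for byte. All stochastic learners are seeded and
single-threaded.

The study configuration is a 60 × 60 grid (0.5° cells) with 12 countries,
30 virtual species, 5 algorithms × 10 replicates, and 2 scenario families
× 3 horizons — sizes chosen so a full run is a coffee-break job on a
laptop core while keeping ≈ 300 cells per country, enough for meaningful
ranges, buffers and hotspots. The smoke configuration (20 × 20, 2
countries, 6 species, 3 algorithms × 3 replicates) exercises every code
path in seconds.

# Known limitations

* Raster I/O is plain long-format CSV keyed by cell index; there is no
  georeferenced binary raster writer.
* The scenario drift is spatially uniform; there is no regional structure
  in the perturbation beyond what the baseline fields supply.
* The ensemble supports only the weighted-mean consensus (no median/mode
  committees), mirroring the single consensus rule of the workflow it
  implements.
* Pseudo-absences are drawn from M, which necessarily contains part of the
  true range; this contamination caps achievable discrimination and is the
  main driver of threshold bias in range recovery. The recovery tests
  therefore compare the binary map restricted to M against the true range.
* CV summaries, richness maps and profiles are computed on the synthetic
  world only; no claim is made about their magnitudes on real data.
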