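---
title: "Methods: image-based growth rates, water-use indices and heritability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based growth rates, water-use indices and heritability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenogrowth)
```

`phenogrowth` implements a screening protocol for pot experiments under
contrasting soil-moisture regimes: predict shoot fresh biomass from plant
silhouette images, differentiate it into growth rates, normalise by measured
water use, and ask whether the resulting traits are heritable. This vignette
explains the models behind each stage, the tunable parameters and their
defaults, what the synthetic-experiment generator does and does not emulate,
and the numerical choices and limitations a user should know about.

## Experimental units and conventions

One record is one **pot** — pots may carry several seedlings, but replication
and imaging are per pot, so per-plant values are at most a reporting division
downstream. Days are integer **days after treatment** (DAT), day 0 being the
day stress is imposed. Water mass and volume are interchangeable at
1 g ≡ 1 ml, the standard gravimetric convention.

## Image features

Plants are segmented from each view (top, and side views at 0° and 90°) by
nearest-neighbour colour classification: every pixel in a configurable
region of interest is assigned the class of its nearest reference colour in
RGB Euclidean distance. Classification happens in raw RGB space by default
because that is the classic chamber-software behaviour; the reference sets
are user-supplied. Speckle noise is removed by erosion then dilation with
disc structuring elements, components below a minimum area are dropped, and
the survivors are treated as a single composed object. A segmentation that
retains no pixel is a *missing observation*, not an error: the plant-day row
is kept with all features flagged absent.

Fourteen geometric descriptors are computed per view — projected area,
convex-hull area, perimeter, hull perimeter, bounding-box width and height,
maximum caliper length, compactness, eccentricity, centroid height,
solidity, aspect ratio, extent and equivalent diameter — giving the
14 × 3 = 42 geometry-only predictor block used for biomass modelling. The
choice of fourteen is a package decision designed to reproduce that
42-column predictor structure while covering the size, shape and
distribution descriptors such software typically emits; the registry
(`pg_feature_registry()`) is the single source of truth and extensible. The
two side views are kept as separate columns rather than averaged. Mean NIR
gray (8-bit) under the RGB-derived mask is carried alongside as a tissue
water-content proxy — higher reflectance means drier tissue — but is
excluded from the geometry-only block.

Numerical notes: perimeter is the traced 8-connected contour length (unit
and √2 steps), which makes the isoperimetric compactness 4πA/P² of a
rasterised disk land near 1 but occasionally a hair above it, so compactness
is clamped to (0, 1]. The convex hull is taken over pixel *corner* points
rather than centres so that `area ≤ hull_area` holds for every mask,
including thin or single-row ones. No pixel-to-millimetre calibration is
applied: with fixed camera geometry and limited height variation, features
stay in pixels.

## Biomass model comparison and selection

Only the final (harvest) day has measured fresh biomass, so the model
comparison resamples that single day rather than holding out a test set:
repeated k-fold cross-validation (default 10-fold, 5 repeats, 50 resamples)
or 25-replicate bootstrap with out-of-bag scoring. Eight families are
compared: ordinary least squares (LM), forward–backward stepwise selection
under an AIC penalty (SM), principal-component regression (PC), partial
least squares (PLS, NIPALS algorithm), elastic net, random forest, gradient
boosting and multivariate adaptive regression splines (MARS, grown forward
as hinge-function pairs and pruned backward by generalised
cross-validation). MARS and PLS are implemented in-package; PLS at full
component count reproduces OLS to numerical precision, which the test suite
uses as an oracle.

Per resample, mean imputation, centring and scaling are estimated on the
training split only. Hyperparameters are tuned caret-style: held-out
predictions are produced for every grid row on every resample and the row
with the lowest mean held-out RMSE wins. Default grids: PLS/PC components
1..min(20, p); elastic-net mixing {0.1, 0.55, 1} crossed with eight
log-spaced penalty fractions of the data-derived maximum; random forest
mtry {p/3, 2p/3, p} at 300 trees; boosting depth {1, 2, 3} × {100, 300}
rounds at learning rate 0.1; MARS at most {9, 15} terms. These grids are
package choices — deliberately small enough that the full comparison runs in
minutes at the default study size (144 pots × 42 predictors).

Three metrics are reported per resample: MAE = mean |observed − predicted|,
RMSE = √(mean squared error), and R². R² is reported as the squared Pearson
correlation between held-out observed and predicted values — the bounded
[0, 1] form usual in resampled comparisons — with 1 − SSres/SStot stored
alongside (`R2_ss`); the two agree whenever the prediction is an affine
rescaling of a least-squares fit, and the hand-computed fixtures in the
tests exercise both. For any input RMSE ≥ MAE, with equality exactly when
all residuals share one magnitude.

Selection ranks families by mean resample RMSE (ties: mean MAE, then −mean
R²). Among families within **one resample standard error** of the best, the
smallest *complexity* wins — components for PLS/PC, selected terms for
SM/MARS, non-zero coefficients for the elastic net, the full predictor count
for LM, and effectively unbounded for the ensembles. On collinear
predictors with low-rank structure this systematically prefers a
component-based family that reaches near-minimal error with few components,
which is the behaviour a practitioner wants from such a comparison. The
selected model is refit on all pots and double-checked with a fresh 10-fold
cross-validation reporting per-fold and pooled residual sums of squares and
an F-test of the observed ~ predicted regression. Information criteria
(AIC/BIC) are deliberately not used for the cross-family comparison: several
families have no likelihood or no meaningful parameter count.

Per-day biomass prediction applies the selected model to every plant-day
row. Predictions below a floor ε = 0.01 g are clipped to ε and flagged; the
floor exists to keep downstream logarithms defined. A caveat documented
here because it is visible in the outputs: the model is trained on
harvest-day (large) plants, so early-day predictions are extrapolations and
their relative error is larger than the cross-validated error suggests.

## Growth rates

Each pot's predicted-biomass trajectory is smoothed with a cubic smoothing
spline. The default equivalent degrees of freedom is
`min(5, n_distinct_days − 1)` — enough to follow a sigmoid trajectory over a
few weeks of daily imaging without chasing day-to-day prediction noise — and
is user-settable. Fewer than four distinct days cannot support a cubic
smoothing spline: the series is returned as all-missing with a warning
record rather than an error, so sparsely observed pots degrade gracefully.
Missing biomass values are dropped before fitting.

Interval rates are computed from the **smoothed** values at the window
endpoints: AGR = ΔS/Δt (g d⁻¹) and RGR = Δln S/Δt (g g⁻¹ d⁻¹), with
pointwise AGR(t) = S′(t) and RGR(t) = S′(t)/S(t) from the spline's analytic
derivative. Default windows are 2–6, 5–12 and 2–12 DAT — early vigour, the
establishment of the stress contrast, and their union — and all windows are
parameters, since different studies emphasise different phases. Evaluation
outside the fitted day range is refused rather than extrapolated. Under
exponential growth RGR is window-invariant and equals the rate constant,
which the tests verify both analytically and on noisy simulations.

## Water use

Daily water use is the evapotranspiration between waterings,
WU(d) = weight_after(d−1) − weight_before(d); it includes soil evaporation,
uncorrected, because the screening trait is *productive use of delivered
water*, not transpiration efficiency. Gaps in the weighing record are filled
by spreading the observed loss uniformly across the missing days and
flagged; negative computed values beyond tolerance are floored at zero and
flagged as data-quality issues. %FC(d) = 100·(weight − tare − dry soil)/FC
tracks the watering targets (defaults 80% well-watered, 50% stressed).

The indices: WUI_BM = 1000·PFB/WUCum (mg ml⁻¹, so WUI_BM·WUCum/1000 ≡ PFB
exactly), and WUI_AGR, WUI_RGR divide the window growth rates by the water
used within the window. Denominators are per pot; division to per-plant
values is left to reporting. Zero denominators yield an undefined-index
signal rather than an infinity.

## Heritability and genotype comparison

For a daily derived trait (the pipeline computes WUI_BM, WUI_AGR and
WUI_RGR per day over a configurable window, by default the first three
weeks of stress), two companion REML models are fitted with `lme4`:
genotype **random** — with replicate, treatment and DAT (categorical) fixed
and G×T, G×DAT, G×T×DAT random — for σg² and BLUPs; and genotype **fixed**
for BLUEs. Constant factors drop out automatically, so the same code covers
a balanced one-way trial.

* Standard: H² = σg²/σp², with σp² composed on the genotype-mean basis —
  each interaction variance divided by the number of levels over which a
  genotype mean averages, and the residual by levels × replicates. The
  composition is a documented convention, since a multi-factor σp² is not
  otherwise uniquely defined.
* Cullis: H² = 1 − v̄ΔBLUP/(2σg²), where v̄ΔBLUP is the mean variance of a
  difference of two genotypic BLUPs, obtained from the prediction-error
  variance block of the mixed-model-equation inverse
  (PEV = σe²·[C⁻¹]gg). Clamped to [0, 1]; defined as 0 at σg² = 0.
* Piepho: H² = σg²/(σg² + v̄ΔBLUE/2), with v̄ΔBLUE the mean pairwise variance
  of a difference of genotype BLUEs from the fixed-genotype fit.

On balanced data the three agree closely; they diverge under unbalancedness,
which is their point. Random-term variances estimated at (near) zero are
dropped from the MME with their effects fixed at zero, which keeps the
G-matrix invertible. Note a calibration fact verified in the tests: with a
null genotypic variance the REML estimate is a folded boundary statistic,
so small designs (e.g. 24 genotypes × 3 replicates) still produce nominal
H² estimates above 0.1 in roughly a third of null runs — detecting "no
heritability" reliably needs many genotypes, not merely more replicates.

ANOVA uses Type-II sums of squares on a linear model; residual normality is
checked by Shapiro–Wilk at α = 0.05 and, when rejected, the response is
log(x + offset)-transformed and refitted, with the transform recorded.
Genotype means are compared with Duncan's multiple range test: for a span of
r ordered means the critical range is
R_r = q(1 − (1−α)^(r−1); r, df)·√(MSE/n_h), with studentized-range quantiles
computed numerically (inverting the distribution function when the quantile
routine fails to converge at large r) and the harmonic mean group size for
unequal n (flagged). Duncan's protection rule applies: a pair inside a
non-significant wider span is itself non-significant, which gives the
compact letter display the interval property — each letter covers a
contiguous run of ordered means. The test suite checks the display against
an independent brute-force all-pairs implementation. Duncan's protected
levels make the procedure more liberal than a familywise test: for k null
groups the probability that all share one letter is exactly (1−α)^(k−1).

## The synthetic-experiment generator

`simulate_experiment()` emulates the study conditions end to end: G
genotypes × 2 treatments × R replicate pots observed daily. Latent biomass
follows logistic growth B(d) = K/(1 + ((K−B0)/B0)e^(−rd)) with
r = base_rate·exp(u_g)·m_t, genotype log-rate effects u_g ~ N(0, σ²_rate)
and a stressed-rate multiplier m_t. Defaults: 24 genotypes, 3 replicates,
26 days, B0 = 5 g, K = 40 g, base rate ln(7)/25 d⁻¹ and multiplier 0.45 —
chosen so a well-watered pot roughly quadruples and a stressed pot roughly
doubles over the experiment, the qualitative contrast such trials show. The
absolute biomass scale is a package choice. An exponential mode with
constant RGR exists for analytic growth-rate tests. Pots hold 14 kg of dry
soil with 3.5 kg of water at field capacity and are topped up daily to
80%/50% FC target weights; daily use is transpiration (10 ml per g biomass
per day) plus evaporation (50 ml d⁻¹) with small Gaussian noise, and the
ledger's weight arithmetic is exact by construction.

Image features are allometric transforms of biomass — projected areas ∝
B^(2/3), linear sizes ∝ B^(1/3), perimeters ∝ √area, shape ratios roughly
constant — under multiplicative lognormal noise (5% signal noise per
plant-day, 5% extra per feature), and NIR gray is inversely affine in a
tissue-water fraction that tracks the watering target and drifts drier
under stress. `render_plant_images()` additionally rasterises elliptical
green blobs (with optional salt noise) whose foreground pixel count matches
the requested area exactly, for testing the segmentation path.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: plant architecture (leaves, petioles,
overlap, rotation asymmetry between the two side views), occlusion and
lighting artefacts in segmentation, temporally autocorrelated prediction
errors, genotype-specific allometry, recovery dynamics after rewatering,
and mortality. Results on synthetic data validate the *computations*; the
biology still has to come from a real experiment.

## Problem sizes and determinism

Everything is deterministic under fixed seeds: simulation, fold assignment,
the ensemble learners (single-threaded, seeded) and hence entire pipeline
reports. The test suite and the acceptance script run the full
eight-family comparison at the default 144-pot scale and the replicated
property checks (heritability calibration, selector behaviour, planted-
genotype recovery) at reduced scales — 8–10 genotypes, 14 days, one or two
fast families — sizes chosen so the whole suite completes in a few minutes
while still exercising every code path at the study's structure.

## Known limitations

* Early-day biomass predictions extrapolate a harvest-day model (see above).
* One model is pooled across both treatments; fitting per treatment is
  possible by subsetting upstream but is not a built-in option.
* The stepwise family uses a fast AIC forward–backward search on the scaled
  design, not the formula-interface `step()`; coefficients match, paths may
  differ on ties.
* v̄ΔBLUP is computed from a dense mixed-model-equation inverse; with very
  many random-effect levels (tens of thousands) this would need a sparse
  solver.
* The Duncan test is intentionally the classic liberal procedure; users
  wanting familywise control should use a different comparison.
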