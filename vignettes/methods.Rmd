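---
title: "Methods: PMI estimation from plasma ATR-FTIR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PMI estimation from plasma ATR-FTIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Blood plasma sampled after death carries a time stamp: as cell membranes lose
integrity, intracellular material from the formed elements (dominated by
hemoglobin in erythrocytes) leaks into the plasma, and the plasma
mid-infrared absorbance spectrum drifts toward the formed-element spectrum.
`plasmapls` treats PMI estimation as a multivariate calibration problem on
this drift: a PLS1 regression of PMI (hours) on the preprocessed 1800–900
cm⁻¹ spectrum, with wavelength selection, diagnostics and similarity
analyses around it.

The package assumes spectra arrive as wide tables (one row per spectrum,
numeric wavenumber columns in cm⁻¹, descending axis canonical) with a PMI
label per sample; replicate spectra of one sample are averaged before
modeling.

## Preprocessing

Two steps, in a fixed order:

1. **SNV** (standard normal variate): each spectrum is centered and scaled to
   unit standard deviation across wavenumbers. This removes multiplicative
   scatter and additive offsets exactly; every corrected spectrum lies on the
   sphere of radius √(p−1).
2. **Savitzky–Golay second derivative**, window 7, polynomial order 2. The
   second derivative sharpens overlapping bands and annihilates any residual
   linear baseline. The 7-point order-2 kernel is (5, 0, −3, −4, −3, 0, 5)/42
   (identical for polynomial order 3); it is exact for quadratic sequences.

Numerical choices worth knowing:

* Derivatives are per-index², not per-(cm⁻¹)²: no division by the axis
  spacing squared. PLS is equivariant to a common column scaling, so
  downstream results are unchanged; the provenance record notes the steps
  applied.
* The default edge policy `shrink` drops (window−1)/2 = 3 points per side
  (467 → 461 points) instead of inventing padded estimates; `reflect` is
  available. When raw spectra extend beyond 1800–900 cm⁻¹, preprocess first
  and slice afterwards (the pipeline runner does this), so no analysis points
  are lost to the filter edges.
* Whether SNV should be computed on the full recorded range or after slicing
  is unknowable from typical method descriptions; the pipeline default is
  preprocess-then-slice, and both orders are reachable through the exported
  functions.

## PLS1, latent-variable choice, and evaluation

The NIPALS recursion on mean-centered data (no variance scaling — derivative
spectra share one scale): for each latent variable, w ∝ Xᵀy (normalized),
t = Xw, p = Xᵀt/tᵀt, q = yᵀt/tᵀt, then X and y are deflated. The regression
vector b = W(PᵀW)⁻¹q reproduces the score-recursion predictions exactly, and
scores of different LVs are orthogonal — both are tested invariants, and the
whole fit is cross-checked against an independent Krylov-subspace closed form
of PLS1 in the test suite.

The LV count is chosen from the leave-one-out RMSECV curve by a greedy 5%
rule: accept LV a+1 only while RMSECV improves by at least 5%; ties count as
failures; the first failure stops the search. This is deliberately
conservative — flat curves yield one LV.

Evaluation reports RMSECV and RMSEP (hours), RE% = 100·RMSE/mean(actual y of
the evaluated set), R², cumulative explained X-variance, and RMSEP/RMSECV
with the conventional < 1.2 robustness flag. R² is the squared Pearson
correlation between actual and predicted (the 1 − SSE/SST variant is also
carried in the report object, `r2_cv_sse` / `r2_pred_sse`, for auditability).
`max_lv` defaults to 15 and is additionally capped at n/3 to bound the LOO
cost.

## Outlier screening

Three diagnostics are computed at the LV count chosen on the full calibration
set: leverage hᵢ = 1/n + tᵢᵀ(TᵀT)⁻¹tᵢ (Σh = A+1), Q-residuals
Qᵢ = ‖xᵢ − x̂ᵢ‖² from the A-LV reconstruction, and Studentized y-residuals of
the LOO predictions, rᵢ = eᵢ/(s√(1−hᵢ)) with s² = Σe²/(n−A−1). A sample is
removed when **two of three** criteria fire: h > 3(A+1)/n, |r| > 3, or Q
above its empirical 95th percentile. Design rationale:

* The voting rule avoids single-criterion brittleness when no published
  thresholds exist; `strict` (any one criterion) and `off` are available.
* The Q threshold is the empirical 95th percentile rather than the
  Jackson–Mudholkar closed form — distribution-free and adequate at n ≈ 70.
* A guard aborts if a policy would remove more than 20% of samples.
* One caveat discovered in testing: the NIPALS reconstruction TPᵀ is an
  oblique projection, so the Pythagorean split ‖x_c‖² = explained + Q holds
  exactly in aggregate (Frobenius norm) but not per sample; the per-sample
  properties that do hold exactly (Q = 0 in the model plane, Q = ‖v‖² for an
  increment orthogonal to the model span) are what the tests assert.

## GA-PLS wavelength selection

Variables are first binned — means of 3 contiguous wavenumbers, remainder in
a final short bin (467 → 155 triples + 1 pair = 156 bins) — and a binary
chromosome over bins is evolved. Fitness is the 5-fold venetian-blind
cross-validated explained variance, 100·(1 − PRESS/SSy), with the LV count
picked by minimum CV error up to `fitness_max_lv` = 10. (Venetian blinds, not
LOO, keeps 100 replicate runs tractable; final model evaluation still uses
LOO.)

The search is **steady-state**: each new chromosome comes from two
tournament-of-3 parents by single-point crossover (probability 0.5) and
per-gene mutation (0.01), and replaces the current worst individual only if
fitter. The best chromosome can therefore never be lost, which is how the
elitism guarantee (best-so-far fitness non-decreasing) is met. A fitness
cache stops re-visited chromosomes from consuming the evaluation budget
(200 per run by default), mirroring how the classical small-budget GA-PLS
recipes spend their evaluations; in our calibration experiments a
generational scheme with elitism 2 recovered planted informative bins far
less reliably at tight budgets. Empty chromosomes are repaired by switching
one random gene on.

Across the default 100 replicate runs (seeds derived from the master seed by
counter, so runs are order-independent), per-bin selection frequencies are
aggregated and bins retained iff selected in **strictly more than 50%** of
runs; retained bins expand to their original wavenumbers for the final
GA-PLS model. If nothing clears the threshold the top-10 bins are retained
with a warning. Backward-stepwise hybridization of the classical toolbox is
deliberately omitted.

## Similarity and trend statistics

Cos²(x, y) = (Σxᵢyᵢ)²/(Σxᵢ²·Σyᵢ²) measures directional match of two spectra
(bounded, symmetric, scale-invariant). Profiles are computed on preprocessed
spectra against the mean preprocessed 0-h formed-element spectrum — in the
synthetic world the formed endmember plays this role — over three masks:
full spectrum, GA-selected, GA-excluded (a disjoint partition of the axis).
Raw-spectrum profiles are equally possible by passing unpreprocessed data.

Group trends (similarity or A414 vs PMI) use a one-way ANOVA by direct
between/within decomposition (the direct form keeps the 2000-replicate
type-I-error calibration in the test suite fast; it is cross-checked against
`stats::anova(stats::lm(...))`). Post hoc pairwise comparisons use Fisher's
LSD (pooled-variance t, no correction) when Levene's test (center = mean)
does not reject variance homogeneity at 0.05, and Tamhane's T2 (Welch t with
Šidák correction) otherwise — "Tamhane" without qualification is read as T2.
The A414 analysis compares every PMI group to the 0-h baseline and flags
p < 0.05, the star convention of the usual bar plot.

## The synthetic world

The generator exists so that every stage has a stated, testable ground
truth. It emulates:

* Two endmember spectra as sums of Gaussians at the canonical plasma band
  positions (1650, 1633, 1628, 1541, 1511, 1455, 1396, 1313, 1240, 1122,
  1080, 1040 cm⁻¹). Amplitudes encode the key scientific contrast: plasma
  (albumin, globulins, lipids, sugars, phosphates) has rich fine structure,
  while the formed-element film is hemoglobin-dominated — one broad α-helix
  amide I envelope with weak fine structure (hemoglobin is ~90% of
  erythrocyte protein). The largest endmember difference thus falls in the
  amide I/II region.
* Postmortem redistribution as a mixing fraction
  α(t) = α_max(1 − e^(−t/τ)), α_max = 0.7, τ = 12 h: α(36 h) ≥ 95% of the
  ceiling, producing the observed late plateau. No kinetic law is claimed;
  a saturating exponential is the simplest curve with the right shape.
* Measurement nuisances: multiplicative scatter U(0.95, 1.05), baseline
  offset U(−0.02, 0.02) and slope U(−10⁻⁶, 10⁻⁶) per cm⁻¹, additive noise
  N(0, 2·10⁻⁴ AU) — a typical 32-scan ATR noise floor. Sample model:
  x(t) = s·[(1−α)·plasma + α·formed] + b₀ + b₁ν̃ + ε.
* The study designs: calibration 0–48 h every 6 h × 8 (72 samples),
  prediction 3–45 h every 6 h × 3 (24 samples), 467 points on 1800–900 cm⁻¹;
  optional replicate spectra per sample with a parent map for averaging.
* A414 (Soret band) values a₀ + gain·α(t) − dip·max(0, t−42)/6 + noise,
  rising with PMI and dipping slightly at 48 h.

What it does **not** emulate: physically realistic IR radiative transfer,
Lorentzian/Voigt line shapes, band shifts or width changes with time,
decomposition chemistry beyond the mixing plateau, or full UV-Vis spectra. A
green test on this world therefore establishes correctness of the
*computation*, not field performance on cadaver plasma.

### An information-theoretic caveat, and what "noise small" means

The synthetic drift is one-dimensional: the noiseless mixture is affine in
α(t). After SNV every channel becomes (a + b·α)/σ(α) with σ²(α) a fixed
quadratic, so the entire preprocessed curve spans only two centered
directions — all a linear model can ever use here. The first direction gives
R²_pred ≈ 0.89; the second, which carries the late-PMI (plateau-region)
information, is two orders of magnitude weaker and is swamped by any
realistic per-sample scatter/baseline jitter. Parameter-recovery tests that
demand R²_pred ≥ 0.9 are therefore run in the near-noiseless limit of the
default design (noise 10⁻⁵ AU, scatter and baseline disabled), where the
5%-rule picks 2 LVs and recovery approaches the analytic information cap.
This is a property of the stated world, not of the estimator: real spectra
are not rank-one in this way.

The endmember amplitude defaults were fixed once, at design time, from this
cap analysis (the geometry of the endmember difference controls σ(α) and
hence the cap) together with the hemoglobin rationale above, and have not
been revisited since.

## Reproducibility

All randomness flows from labelled seeds: a master seed spawns per-stage and
per-GA-run seeds by hashing `master:label`, so adding a stage or reordering
runs never perturbs another stage's stream. The same configuration and seed
give byte-identical pipeline reports (timestamps are excluded from the
report). Spectra CSVs are written with 17 significant digits and read back
with the base strtod parser, so write/read round trips are bit-exact.

## Known limitations

* PLS1 only (univariate response); no PLS2, kernel PLS, or prediction
  intervals.
* The GA does not implement backward-stepwise refinement; selection quality
  at very tight evaluation budgets depends on the planted signal being
  spread across complementary bins.
* Outlier thresholds are heuristics with a configurable policy, not a claim
  about the original screening constants, which are not published.
* The similarity analysis defaults to derivative spectra; raw-spectrum mode
  exists but the choice is a documented convention, not a derivation.
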