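---
title: "Quantifying bone use-wear from 3D surface texture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bone use-wear from 3D surface texture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bone tools archive their history in their microtopography: manufacturing
(grinding with sandstone, scraping with flint) and subsequent use against
different materials (fresh skin, processed leather, dry bark) each leave
characteristic traces at the 1–100 µm scale. `osteotex` implements a
quantitative workflow for studying this process: confocal height maps are
cleaned by a metrological preprocessing chain, summarised by four ISO 25178
areal texture parameters, and analysed with a multilevel multivariate
Bayesian mixed model that separates experimental effects (manufacturing
state, material, time) from nuisance structure (scan location, bone vs.
mold replica, re-scanned molds) and idiosyncratic variation (specimen,
acquisition lot).

Because no raw scan archive accompanies the study design this package
emulates, the package ships a first-class synthetic-data module: a
mechanistic surface simulator, a registry generator reproducing the
experimental design (37 bone specimens in 5 acquisition lots, molded over
time for 239 physical samples), and a fast parametric observation generator
mirroring the fitted model's own generative structure.

## Texture parameters

Four parameters, one per ISO 25178 family, summarise each preprocessed
height map `z(x, y)` (µm, measured cells only):

* **Sa** (height family): mean absolute deviation from the mean plane.
* **Sal** (spatial family): the shortest lag at which the normalized
  autocorrelation function (ACF) decays to `s = 0.2`. The ACF is estimated
  by FFT of the mean-removed, mask-zero-filled surface and normalized by
  its zero-lag value; Sal is the minimum physical distance over all
  discrete lags whose ACF value is at or below the threshold. We use the
  discrete-lag definition (rather than interpolating between lags) because
  it makes the value exact for the two canonical calibration surfaces: an
  uncorrelated surface gives exactly one sample spacing, and a sinusoid of
  wavelength λ gives the first lattice lag past `(λ/2π)·arccos(0.2)`,
  within half a spacing. The threshold 0.2 is the customary default; the
  study this emulates does not state its value.
* **Spc** (feature family): arithmetic mean peak curvature,
  `-(1/2n) Σ (∂²z/∂x² + ∂²z/∂y²)` over significant peaks, second
  derivatives by 3-point central differences. Significant peaks are strict
  local maxima that survive pruning by topographic prominence at 5 % of
  the total height Sz — the discrete equivalent of watershed Wolf pruning:
  a peak whose height above its key saddle is below the threshold is
  merged into its dominating hill. Prominence is computed by a
  descending-height union–find pass (C++), and the test suite checks exact
  agreement with an exhaustive flood-fill saddle search. Peaks on the grid
  border or beside non-measured cells carry no curvature estimate and are
  skipped.
* **Smr1** (functional family): upper material ratio from the areal
  Abbott–Firestone curve by the equivalent-line construction: the flattest
  40 %-wide window of the material-ratio axis (sampled every 0.5 %) is
  fitted by least squares, the fitted line is evaluated at mr = 0 %, and
  Smr1 is the percentage of material *strictly above* that height. The
  strict inequality matters only for surfaces with exactly tied heights
  (an ideal plateau): it makes a linear ramp score exactly 0 % and keeps a
  plateau-and-pit surface in the few-percent range, which is the intended
  reading of the construction. Smr1 grows when material accumulates above
  the extrapolated core line — i.e. with positive skew of the height
  distribution.

All four are computed from measured cells only; non-measured cells act as
barriers for the peak segmentation.

## Preprocessing chain

`preprocess_pipeline()` applies, in order: least-squares leveling; mold
mirroring (y-flip and z-negation, so mold scans compare directly to bone
scans); robust outlier removal; hole filling; a Gaussian S-filter; and
degree-2 polynomial form removal. Scans with less than 95 % of cells
measured are refused (inclusive bound at exactly 95 %).

Numerical choices:

* *Outliers*: cells whose residual from a 5×5 median surface exceeds
  3×MAD of all residuals ("normal strength") are set non-measured. The
  threshold has a floor of `Sq/2` so that deterministic sharp texture
  (furrow edges) is never eaten — only isolated artefacts well above the
  surface's own roughness scale are flagged. 8-connected non-measured
  regions smaller than 225 points are eligible for filling; larger holes
  stay non-measured.
* *Filling*: harmonic (iterative 4-neighbour mean) inpainting to a 1e-6 µm
  tolerance; it reproduces locally planar surfaces exactly.
* *S-filter*: frequency-domain Gaussian with 50 % amplitude transmission
  at the cutoff wavelength (`a(λ) = exp(−π(α·cutoff/λ)²)`,
  `α = √(ln2/π)`). The default cutoff is 5 µm — about three sample
  spacings of the default 0.8 mm / 512 px field — chosen to suppress
  instrument noise while passing the 5–10 µm use striations; the emulated
  study names no cutoff, so it is exposed in `preprocess_config()`.
* *Form removal*: least-squares fit of the six monomials up to degree 2,
  subtracted; residuals are orthogonal to the fitted basis to numerical
  precision.

## The statistical model

The observation matrix `Y` holds natural logs of the four parameters (all
strictly positive), one row per modeled scan. Time enters as
`log(minutes + 1)`, so time-0 scans form the baseline. The model ladder:

* `M0`: intercept + random effects only;
* `M1`: + scan location (grouped C / L+R / D+P), bone-vs-mold, rescan
  flag, log time;
* `M2`: + manufacturing state and its interaction with log time, and
  material × log time;
* `M3`: + the three-way state × material × log time interaction
  (16 fixed-effect columns under the dummy coding below).

Material has no main effect: every material term is multiplied by log
time, since at time 0 no material has yet touched the surface. Baselines
are location C, bone, non-rescan, state UW (unworked) and material DB (dry
bark); the choice affects interpretation of individual coefficients, not
the fit. The random design `Z` carries one 0/1 column per specimen and per
lot (42 columns for the default registry), two ones per row.

The observation level is multivariate Student-t with scale `Σ = D Ω D` and
degrees of freedom ν (heavy tails absorb over-dispersion relative to a
Gaussian); specimen and lot random intercepts are multivariate Gaussian
with their own `D Ω D` decompositions. Priors: `N(0, 5²)` on fixed
effects, half-Cauchy(2.5) on all scale diagonals, LKJ(1.5) on correlation
matrices, and Gamma(shape 2, rate 0.1) truncated at 2 on ν.

### Sampler

The posterior is sampled by a blocked Gibbs scheme written in
RcppArmadillo, exact by construction (no approximations to the target):

* the t likelihood uses its Gamma scale-mixture representation, making
  the mixture weights, `B`, and `U` conjugate Gaussian/Gamma updates;
* each random-effect scale matrix is updated with its `U` block
  *integrated out* (the group marginal is Gaussian given the weights),
  then `U` is redrawn — a collapsed update that removes the usual
  funnel between effects and their scale;
* scalar scales and ν move by univariate slice sampling on log
  coordinates (tuning-free); correlation matrices move by adaptive
  random-walk Metropolis on their off-diagonals with positive-definite
  rejection, targeting the LKJ-weighted conditional (adaptation during
  warmup only);
* two interweaving moves resample likelihood-invariant translations: the
  common location shared by the intercept and the random-intercept means,
  and, per lot, the shift between a lot's effect and its member
  specimens' effects. The latter is what makes the variance exchange
  between the two grouping factors mix well when lots partially confound
  design cells.

The default configuration (two chains of 500 warmup + 500 kept draws,
stored as 1000 posterior samples) reports split-R̂ for all fixed effects,
scales and ν; a fit with max R̂ > 1.05 is returned flagged rather than
erroring, so model-ladder runs always complete.

### Posterior summaries

`compute_waic()` scores out-of-sample prediction with one "point" per
4-vector scan row (matching the multivariate likelihood);
`waic_table()` builds the Δ-table relative to the best model.
`compute_icc()` reports, per texture parameter, the share of unstructured
variance attributable to lot and to specimen, with the error variance
taken as the Student-t variance `scale² · ν/(ν−2)`.
`mahalanobis_gof()` compares scaled squared Mahalanobis residual distances
`d²/p` with F(p, ν̂) quantiles — the exact reference distribution under
the multivariate-t model — for QQ-plot checking.
`posterior_trajectories()` and `posterior_ellipses()` summarise predicted
means over time and 95 % contours for parameter pairs; back-transformed
values are geometric means on the original scale.

## The synthetic-data generators

`build_registry()` reproduces the experimental design deterministically:
37 specimens in 5 lots, states and materials crossed by cycling through
the 9 cells, molds at 0/30/60/90 minutes and 90-minute intervals
thereafter. The published design reports 239 physical samples (37 bones +
202 molds) but not the per-specimen durations; with the duration set
{180, 270, 450} min, the mix 28/5/4 is the configuration that reproduces
the printed totals exactly, so it is the default. Five scan locations per
sample give 1195 modeled scans; by default the final molds of the
longest-running specimens are duplicated as rescan rows (the one-year mold
stability check), giving 1215 rows. The reported row count of the emulated
study (1253) is not exactly reproducible from its text; the generator
makes no attempt to match it.

`simulate_base_surface()` builds time-0 microtopography: a fine
anisotropic lamellar background (correlation lengths 6 µm along the grain,
2.5 µm across), shallow pores (0.5–2.5 µm deep, 4–25 µm radius, 30/mm²),
plus dense fine transverse scratches (8–16 µm wide) for ground bone and
sparse deep furrows (30–100 µm wide, 2–8 µm deep) for scraped bone. Pore
depth is kept below the background amplitude so that the autocorrelation
length ordering UW < GS < SF reflects the manufacturing traces, as
reported for the real surfaces; deep pores would otherwise dominate the
ACF.

`apply_wear()` erodes a surface by material-specific mixtures of three
modes, with first-order kinetics `a(t) = 1 − exp(−rate·t)` and rates
(FS 0.004, PL 0.0008, DB 0.002 min⁻¹) set so fresh skin roughly halves
the Sa of unworked bone by 450 min while leather barely alters it:

* *differential polishing* (fresh skin, weakly leather): the soft matrix
  is levelled toward a low reference plane while coherent hard relief
  (25 % of the area, the high regions of a 20 µm-smoothed copy) resists.
  This is the mode that drives Smr1 *up* with wear: polishing tightens
  the core height distribution while resistant features keep standing
  proud, exactly the positive-skew signature Smr1 measures. A pure
  peak-truncation model was tried first and rejected: under the
  equivalent-line construction a truncation plateau becomes the reference
  band itself, so Smr1 falls — the opposite of the reported trend.
* *rounding* (leather, weakly skin): partial Gaussian smoothing (σ 3 µm).
* *contact-zone truncation* (bark): only the uppermost surfaces are
  abraded flat, the recessed texture below is untouched.

Fine 5–10 µm use striations accumulate with `a(t)`. Zero minutes returns
the input bit-identically. `mold_of()` produces the physical negative
(y-flip, z-negation) with sub-pixel spectral registration jitter
(roughness-preserving) and a slight rounding of the sharpest peaks, so
mirrored mold scans show lower Spc than their bones, as observed for
dental impression materials.

`simulate_observation_table()` skips surfaces entirely and draws log-scale
4-vectors from the model's own generative structure (fixed effects on the
full-interaction design, Gaussian specimen/lot intercepts, multivariate-t
noise). Defaults — SDs 0.20 (specimen) and 0.15 (lot), t scale 0.25,
ν = 5 — imply lot and specimen ICCs near 0.14 and 0.24, inside the ranges
reported for the real data, with most variance left to error. The built-in
true-effect matrix encodes the reported qualitative findings (state
ordering at time 0, fresh-skin decline in Sa/Spc and rise in Smr1, slight
mold deficit in Spc).

### What passing tests do and do not show

The simulators emulate the *statistical signatures* of the experiment —
orderings, trends, variance structure, heavy tails — not bone tribology.
Passing the trend and recovery suites shows that the measurement chain and
the model behave correctly on data with the documented structure; it does
not validate the wear mechanics against real bone, nor does exact numeric
agreement with any proprietary software follow (the Sal threshold, peak
pruning level and Smr1 window are ISO-style defaults, stated above, not
reverse-engineered settings).

## Problem sizes used by the test and acceptance suites

Simulation-based checks run at reduced, documented scales chosen to keep
the full suite in the minutes range on a single CPU: 192²–256² px surfaces
(same 1.5625 µm spacing as the 512² default, hence a smaller field of
view), 20-seed means for trend checks, n ≈ 600–720 rows for fixed-effect
recovery, n ≈ 2000 rows and 25 lots for ICC recovery (lot ICC needs many
lots to be estimable), and 20 replicates of paired M1/M3 fits at n ≈ 300
for the WAIC preference experiment. The fitted-model defaults (2 × 500 +
500) are used wherever the sampler contract itself is under test.

## Known limitations

* The wear model is phenomenological; its rates and shares are fixture
  calibration, not measured tribology.
* Scan locations within a sample are treated as exchangeable given the
  location factor; no spatial correlation between the five loci is
  modeled.
* The correlation-matrix moves are random-walk; for 4×4 matrices this is
  adequate but would slow down for many more responses. Fits report
  split-R̂ so inadequate runs are flagged rather than silently used.
* Sal inherits the lag-grid resolution of the ACF; on coarse grids the
  discrete-lag definition can be conservative by up to one spacing.
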