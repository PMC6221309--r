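# osteotex

Quantitative use-wear analysis on bone surfaces from confocal height maps.

Bone tools record their manufacture (grinding with sandstone, scraping
with flint) and their use against different materials (fresh skin,
processed leather, dry bark) as micrometre-scale surface texture.
`osteotex` provides the full measurement-to-inference chain for studying
that record:

* **Metrological preprocessing** of raw height maps: least-squares
  leveling, mirroring of mold replicas, robust outlier removal, harmonic
  hole filling, a Gaussian S-filter and degree-2 form removal, with a
  95 %-measured quality gate.
* **Four ISO 25178 areal texture parameters**, implemented from scratch:
  arithmetic mean height *Sa* (µm), autocorrelation length *Sal* (µm,
  FFT-based ACF with a fastest-decay lag search at threshold 0.2),
  arithmetic mean peak curvature *Spc* (1/µm, prominence-pruned peaks at
  5 % of Sz, central-difference curvature) and upper material ratio
  *Smr1* (%, equivalent-line construction on the areal Abbott–Firestone
  curve with a 40 % window).
* **A multilevel multivariate Bayesian mixed model**
  `Y = XB + ZU + E` for the log-scale parameter 4-vectors: fixed
  experimental effects (manufacturing state, material × log time, their
  three-way interaction) and controls (scan location, bone-vs-mold,
  rescan), crossed Gaussian random intercepts for specimen and
  acquisition lot, and a multivariate Student-t observation level
  (`Σ = DΩD` scale decompositions, half-Cauchy/LKJ priors, truncated
  Gamma prior on the degrees of freedom). The sampler is a blocked
  Gibbs/slice/Metropolis scheme in RcppArmadillo with collapsed
  scale updates and interweaving moves; it stores 1000 posterior draws
  under the default two chains × (500 warmup + 500 draws).
* **Model comparison and diagnostics**: WAIC with one point per scan
  row, intraclass correlations for lot and specimen (Student-t error
  variance `scale²·ν/(ν−2)`), Mahalanobis goodness-of-fit against
  F(p, ν) quantiles, posterior mean trajectories over time and 95 %
  ellipses for parameter pairs.
* **Synthetic data generators** that emulate the experiment end to end:
  a deterministic registry (37 specimens, 5 lots, mold schedules giving
  239 samples), a mechanistic surface simulator (lamellar background,
  pores, grinding scratches, scraping furrows, material-specific wear
  kinetics, mold replication defects) and a fast parametric observation
  generator mirroring the fitted model's structure.

## Worked example

```r
library(osteotex)

## a scraped-bone surface, cleaned and summarised
hm    <- simulate_base_surface("SF", seed = 42, n_pix = 256)
clean <- preprocess_pipeline(hm, preprocess_config())
round(compute_all_params(clean), 4)
#>      Sa     Sal     Spc    Smr1
#>  2.3961 37.5000  0.2172  1.6068
```

Scraping leaves a rough (*Sa* ≈ 2.4 µm), long-wavelength
(*Sal* ≈ 37 µm) surface whose deep furrows put little material in the
reduced-peak zone (*Smr1* ≈ 1.6 %).

```r
## the full experiment as an observation table, and the model ladder
reg <- build_registry()
reg
#> <experiment_registry> 37 specimens, 5 lots, 239 samples (37 bones + 202 molds)

tab <- simulate_observation_table(reg, seed = 42)
set.seed(42)
sub <- tab[sample(nrow(tab), 400), ]   # desk-scale subsample

fits <- list()
for (m in c("M0", "M1", "M2", "M3"))
  fits[[m]] <- fit_mcmc(table = sub, model_id = m, seed = 1)
waic_table(fits)
#>   model      waic   p_waic delta_waic
#> 1    M0 1095.6774 155.1369 150.024351
#> 2    M1 1064.5308 176.8908 118.877806
#> 3    M2  945.6530 183.0089   0.000000
#> 4    M3  952.9128 192.7490   7.259742
```

Models with experimental effects (M2/M3) beat the random-effects-only and
controls-only models by ~120–150 WAIC points; at this subsample size the
default generator's mild three-way interactions are not worth their extra
parameters, so M2 edges out M3.

```r
compute_icc(fits$M3)$spec
#>   parameter      mean         lo        hi
#> 1        Sa 0.2696280 0.10417189 0.4301877
#> 2       Sal 0.2303394 0.10760341 0.3639255
#> 3       Spc 0.1648222 0.06307075 0.2979409
#> 4      Smr1 0.2234980 0.07464306 0.3713801
```

About a fifth to a quarter of the unstructured variance is attributable
to individual specimens; the bulk stays in the observation-level error.

`run_pipeline(pipeline_config(out_dir, seed = ...))` chains all stages
(simulate → preprocess → parameters → fit M0..M3 → WAIC/ICC/GOF →
figures) and writes a manifest with seeds and file checksums. A thin
command-line wrapper lives at `inst/scripts/osteotex.R`.

## Package layout

```
R/                 height maps & I/O, texture parameters, preprocessing,
                   experiment synthesis, model design/fit/summaries,
                   pipeline & reporting
src/               RcppArmadillo MCMC core, peak prominence (union-find)
tests/testthat/    unit, property and acceptance suites with
                   brute-force oracle implementations
vignettes/         methods vignette (model, parameters, generators,
                   numerical choices, limitations)
scripts/           acceptance script
inst/scripts/      command-line wrapper
```
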