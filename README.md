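# rhogradients

Modelling, simulation, and quantification of Rho GTPase activity gradients
at the front of migrating cells.

During migration, active **Cdc42** forms a steep gradient peaking at the
protruding cell edge, while active **Rac1** peaks a few micrometers inside
and extends further. This package implements, as tested and reusable R
code, the quantitative machinery behind the local activator/deactivator
explanation of these gradients:

* **Steady-state GEF/GAP model.** With fast first-order kinetics and no
  transport, the active fraction is the local rate ratio
  `R*(x)/R_tot = Σ α_i[GEF]_i(x) / Σ β_i[GAP]_i(x)`. Cdc42 follows an
  exponential GEF (decay length λ ≈ 10 µm) over a uniform GAP; Rac1
  additionally sees a tip-localized GAP (β2-chimaerin, length γ = 5 µm),
  giving `Rac1*(x) ∝ α_R e^(−x/λ) / (β_R + β_b e^(−x/γ))` with an interior
  maximum at `x_bump = γ ln((λ−γ)/(rγ))`, `r = β_R/β_b`, which exists iff
  `r < (λ−γ)/γ` (i.e. `r < 1` at the measured lengths). A crosstalk
  refinement makes the localized GAP a linear function of the local Cdc42
  and Rac1 activities and supports in-silico knockdowns.
* **Optogenetic input model.** Gray-level linear light gradients on 35 µm
  round micropatterns (slope classes 1×–4×) and the membrane recruitment of
  the light-dimerized GEF, which adds a 5 µm exponential diffusion tail
  (reflecting boundaries, mass-conserving).
* **Synthetic data generators.** Calibrated per-cell FRET linescan
  ensembles (defaults reproduce the reported summary statistics: Cdc42
  decay 8.3 µm and extent 8.9 µm at n = 19; Rac1 peak 5.8 µm, tail 9.6 µm,
  extent 14.6 µm at n = 31), TIRF-like two-channel image stacks, and
  migration movies with recorded ground truth.
* **Quantification.** Ratio images, pre-stimulus subtraction, 10-px
  linescans, five-extreme normalization, cell-first ensemble averaging,
  decay/peak/extent metrics, pointwise Wilcoxon curve comparison,
  input–output extent matching, and the edge-enrichment fraction.
* **Migration analysis.** Otsu segmentation, centroid tracking, windowed
  instantaneous speed, displacement angles, bootstrap angular precision
  (mean resultant length), von Mises concentration recovery, and
  morphodynamic edge-velocity maps.

## Worked example

Generate calibrated synthetic FRET ensembles at the study's sample sizes
and quantify the gradient shapes:

```r
library(rhogradients)

rep <- run_experiment(preset_native_gradients(seed = 1))
rep$metrics$quantify
#>   species        metric  estimate  n
#> 1   Cdc42      decay_um  8.338194 19
#> 2   Cdc42     extent_um  8.418285 19
#> 3    Rac1       peak_um  6.519758 31
#> 4    Rac1 tail_decay_um  8.856180 31
#> 5    Rac1     extent_um 14.561309 31
```

One 19/31-cell experiment scatters around the generator truths (8.3 / 8.9 /
5.8 / 9.6 / 14.6 µm); averaged over 200 seeded replicates the estimates
recover them within the reported SEMs (see the acceptance script below).

The closed-form bump position of the Rac1 model at the worked rates:

```r
bump_position(10, 5, 0.5)   # lambda, gamma (um), r = beta_R/beta_b
#> [1] 3.465736                # = 5 ln 2 um from the cell edge
```

Directionality statistics of an 18-cell migration condition:

```r
angular_precision(rvonmises(18, 0, 2), seed = 2)
#> <angular_stats> precision 0.724 +/- 0.089 (bootstrap s.d., n = 18)
```

See the methods vignette (`vignettes/gradient-shaping.Rmd`) for the model
assumptions, calibration details, estimator choices, and limitations.

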