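---
title: "Shaping of Cdc42 and Rac1 activity gradients: models, synthetic data, and quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shaping of Cdc42 and Rac1 activity gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(rhogradients)
```

## The scientific problem

At the front of a migrating cell, active Cdc42 forms a steep gradient that
peaks at the protruding edge, while active Rac1 peaks a few micrometers
inside and extends further. Two classes of mechanism could shape such
gradients: transport of an activated species away from a localized source
(diffusion or actin flow), or a purely local balance between distributed
activators (GEFs) and deactivators (GAPs). This package implements the
local-balance model, a forward model of subcellular optogenetic stimulation
used to discriminate the two classes, generators of synthetic data with the
statistical structure of the corresponding microscopy experiments, and the
quantification machinery that turns images and trajectories into the
summary statistics of interest.

## The steady-state GEF/GAP model

With first-order activation/deactivation, fast equilibration, non-limiting
total GTPase, and no transport, the active fraction at position $x$ (µm
from the cell edge) is the local rate ratio

$$\frac{R^*(x)}{R_\mathrm{tot}}
  = \frac{\sum_i \alpha_i [\mathrm{GEF}]_i(x)}
         {\sum_i \beta_i [\mathrm{GAP}]_i(x)}.$$

`steady_state_ratio()` evaluates this for arbitrary lists of uniform,
exponential, or tabulated regulator profiles. Two named special cases cover
the two GTPases:

* **Cdc42** (`cdc42_profile()`): an exponentially distributed GEF of decay
  length $\lambda$ (≈ 10 µm) over a uniform GAP,
  $\mathrm{Cdc42}^*(x) \propto \alpha_C e^{-x/\lambda}/\beta_C$ — a
  monotone, edge-peaked gradient.
* **Rac1** (`rac1_profile()`): the same GEF shape over a uniform GAP *plus*
  a second GAP (β2-chimaerin) localized at the tip with its own length
  $\gamma$ = 5 µm,
  $\mathrm{Rac1}^*(x) \propto \alpha_R e^{-x/\lambda} /
  (\beta_R + \beta_b e^{-x/\gamma})$. The localized deactivator chops the
  profile off at the edge, producing a bell shape whose interior maximum
  sits at

$$x_\mathrm{bump} = \gamma \ln\!\left(\frac{\lambda-\gamma}{r\,\gamma}\right),
  \qquad r = \beta_R/\beta_b,$$

returned by `bump_position()`. A strictly interior bump exists iff
$r < (\lambda-\gamma)/\gamma$, which is $r < 1$ at the measured lengths;
`bump_position()` returns `NA` ("absent") when the expression is negative
so callers can distinguish edge-peaked from bumped profiles, and 0 at the
exact boundary. All rates are in arbitrary units (the FRET readout carries
no absolute scale); the worked defaults are
$\alpha_C=\alpha_R=1$, $\beta_C=\beta_R=0.5$, $\beta_b=1$.

```{r model}
x <- spatial_grid(35, 0.05)
plot(rac1_profile(gtpase_params(), x))
bump_position(10, 5, 0.5)   # = 5 ln 2
```

`diffusion_length()` returns the scale $\ell_\mathrm{diff} = \sqrt{\tau D}$
that a transport mechanism would add to the output of a localized source;
it exists for reasoning about the rejected transport hypothesis and is not
part of the (purely local) model.

### Crosstalk and in-silico knockdowns

Depletion experiments show that the tip GAP is itself driven by Cdc42 and
Rac1. We model its effective rate as a linear function of the two local
activities, retaining an explicit localization factor:

$$\beta_b(x) = \left(\beta_{Cb}\,\mathrm{Cdc42}(x)
  + \beta_{Rb}\,\mathrm{Rac1}(x)\right) e^{-x/\gamma_a},
  \qquad \gamma_a = (1/\gamma - 1/\lambda)^{-1}.$$

The design was genuinely open here: the linear-crosstalk statement does not
say whether an independent localization factor survives once $\beta_b$ is
concentration-dependent. We keep it, for two reasons. First, with
$\gamma_a$ as above the Cdc42-driven component decays exactly with the
directly measured GAP length $\gamma$ = 5 µm, so the refined model reduces
to the minimal one in shape. Second, the factor stands for the
actin/adaptor tip machinery that is experimentally required for GAP
localization (freezing actin dynamics delocalizes the GAP even though the
GTPase activities persist) — without it, knocking down Cdc42 alone could
not delocalize the remaining Rac1-driven component.

Because Rac1 appears on both sides, each grid point yields a scalar
quadratic; `crosstalk_rac1_profile()` takes its unique non-negative root in
closed form (the discriminant is positive by construction). A damped
fixed-point iteration (damping 0.5, tolerance $10^{-10}$) is kept in the
test suite as an independent oracle, and agrees to better than $10^{-10}$
everywhere. Knockdowns are simulated by scaling the targeted rates:
`"cdc42"` scales $\alpha_C$, `"chimaerin"` scales both crosstalk
coefficients; partial siRNA efficiency is a multiplier in $[0,1]$ (default
complete). With the defaults ($\beta_{Cb} = 0.4$, $\beta_{Rb} = 0.3$), both
knockdowns raise Rac1 at the edge and abolish the bump, and the two
knockdowns differ pointwise by well over 5% — the signature of Rac1
self-inhibition, which vanishes identically when $\beta_{Rb} = 0$.

## The optogenetic input model

Gray-level light gradients on 35 µm round micropatterns are described by
`linear_gradient()`: slope class $k\times$ spans $1/k$ of the cell
diameter, so classes share an amplitude but differ in extent and slope;
custom (amplitude, extent) pairs decouple the three properties. Membrane
recruitment of the light-dimerized GEF adds a diffusion tail: the
steady-state Green's function of lateral diffusion with first-order
unbinding is a two-sided exponential of characteristic length
$\ell$ = 5 µm, and `membrane_recruitment()` convolves the illumination with
it under no-flux (reflecting) boundaries at both cell edges, implemented by
the method of images with per-source mass renormalization. Mass
conservation is exact by construction and uniform light maps to uniform
recruitment.

One numerical subtlety matters for the inverse check. On a closed 35 µm
domain the reflecting far edge bends the tail of a step response into
$\cosh((L-x)/\ell)$: even two kernel lengths away from the boundary the
local decay length is ~4% longer than $\ell$, so a naive log-linear slope
cannot recover the kernel length to within a few percent. The default
`fit_tail_length()` therefore fits the boundary-aware shape
$A\cosh((L-x)/\ell)$ (amplitude profiled out, least squares in linear
space so additive noise does not bias the log), which reduces to an
exponential fit far from the boundary; the plain log-linear estimator
remains available via `correct_boundary = FALSE`. With this estimator the
kernel length is recovered within 2% for $\ell \in \{2, 5, 10\}$ µm, and
the simulated mid-cell step response returns the configured 5 µm tail.

`opto_gef_profile()` turns a recruitment profile into a tabulated GEF term
for `steady_state_ratio()`. In the stimulation experiments the optogenetic
rate dominates the endogenous one ($\alpha_\mathrm{opto} \gg \alpha_C$);
at a 100-fold excess the response is within 2% of the pure-optogenetic
prediction.

## What the synthetic data emulate — and what they do not

No imaging data are deposited for this system, so the generators are
first-class, calibrated code whose defaults *are* the study conditions:
per-cell FRET linescan ensembles at the reported sample sizes (19 Cdc42,
31 Rac1 cells), TIRF-like two-channel stacks of 35 µm disk cells, and
migration movies at ~20 cells per condition.

**Mean shapes.** The Cdc42 mean shape is a plateau followed by an
exponential of the reported decay length 8.3 µm. The plateau is forced by
arithmetic: a pure 8.3 µm exponential, window-normalized, crosses
half-amplitude near 6 µm and can never reach the reported 8.9 µm extent,
so the two printed numbers are only jointly consistent if the profile is
flat-topped near the edge (as edge-proximal profiles indeed appear). The
plateau width (~4.4 µm on the default window) is solved by 1D root-finding
so that `measure_extent()` of the noiseless normalized shape hits 8.9 µm
to 0.01 µm. The Rac1 mean shape is the localized-GAP profile itself with
asymptotic tail fixed at the reported 9.6 µm; $(\gamma, r)$ ≈ (6.1 µm,
0.22) are solved by nested root-finding (the inner bracket comes from
inverting the closed-form bump position) so that `detect_peak()` and
`measure_extent()` hit 5.8 and 14.6 µm exactly.

**Windows and normalization.** Profiles are measured on a 20 µm window
(edge to nucleus; the exact length is not reported) with five-extreme
normalization — 0 is the mean of the five smallest and 1 the mean of the
five largest samples. The extent metric depends on both choices; 20 µm is
the calibrated default that makes the printed extents reproducible, and it
is a flagged configuration value, not a constant.

**Noise.** Each cell's linescan is the mean shape times a lognormal
amplitude factor (σ = 0.2, the cell-to-cell FRET variability) plus i.i.d.
Gaussian noise with s.d. equal to 10% of the mean-shape peak; images add
Poisson shot noise and Gaussian read noise on a 0.25 µm pixel grid (so the
conventional 10-pixel linescan width is 2.5 µm). These are the simplest
models matching the reported dispersion bars. Migration movies translate a
smoothly perturbed disk (Fourier boundary modes of order ≥ 2, so the
centroid stays on the ground-truth track) with a protrusive lobe toward a
per-cell heading drawn from a von Mises distribution about the gradient
axis.

Passing recovery tests on these ensembles shows that the estimators are
calibrated and approximately unbiased *under this noise model*. Real
acquisitions add features the generator deliberately omits — irregular
cell shapes, nucleus exclusion, photobleaching, stage drift, optical PSF,
segmentation-confounding debris — so recovery here bounds estimator error,
not experiment error.

## Quantification choices

* **Decay length** (`fit_decay_length()`): nonlinear least squares of
  $A e^{-x/\lambda} + B$ with a free baseline, robust to the nonzero
  far-field FRET signal of non-normalized profiles. The fit range for the
  Cdc42 shape starts at the plateau end.
* **Rac1 tail decay** (`fit_localized_gap_profile()`): the bumped profile
  needs care. Inside a 20 µm window the localized GAP is still relaxing,
  so the post-peak flank is genuinely flatter than the asymptotic tail;
  fitting $A e^{-x/\lambda} + B$ from the peak is ill-posed there (the
  objective keeps improving as $\lambda$ grows). Worse, the three
  reported Rac1 numbers cannot coexist for any windowed exponential: a
  profile whose post-peak decay truly fits 9.6 µm has extent at most
  $5.8 + 9.6\ln 2 \approx 12.5$ µm, short of the reported 14.6 µm. The
  package therefore estimates the tail by fitting the localized-GAP form
  itself over the full window — the rising flank pins $\gamma$ and $r$,
  leaving $\lambda$ well identified (exact on noiseless shapes; mean 9.59,
  s.d. 0.68 µm across 200 noisy 31-cell ensembles).
* **Peak position** (`detect_peak()`): Gaussian smoothing (σ = 0.5 µm,
  edge-renormalized kernel), global maximum with ties broken toward the
  edge, quadratic sub-grid refinement; maxima at either domain end are
  reported as "edge-peaked" rather than numbers.
* **Extent** (`measure_extent()`): first half-amplitude crossing *beyond*
  the maximum, linearly interpolated, so bumped profiles measure their
  decaying flank; no crossing within the window is flagged, not invented.
* **Ensemble averaging** (`average_ensemble()`): replicate linescans are
  averaged within each cell before cells are averaged, so a cell with more
  lines does not dominate.
* **Curve comparison** (`pointwise_compare()`): two-sided Wilcoxon
  rank-sum test at each position, uncorrected for multiple testing as in
  the source figures (Benjamini–Hochberg available, off by default). On
  identical generators the significant fraction sits at the nominal 5%;
  note that shared per-cell amplitude factors correlate positions, which
  widens the replicate-to-replicate spread of that fraction without
  moving its mean.
* **Input–output match** (`profiles_match()`): two profiles "match" when
  their normalized extents agree within the ~2 µm measurement resolution.
  Under a sharp (4×) optogenetic input, a uniform-GAP response mirrors the
  input (match) while a localized-GAP response is reshaped by more than
  2 µm (mismatch) — the discrimination logic separating the two GTPases.
* **Edge enrichment** (`edge_enrichment_fraction()`): the mask boundary is
  cut into 1 µm arcs; each arc compares the mean intensity of the 1 µm
  band just inside the edge against the adjacent 1–2 µm cytosolic band,
  and the fraction of edge-brighter arcs is returned (0.5 for a uniform
  cell, 1 for a full rim).

## Migration statistics

Movies are segmented per frame by a global Otsu threshold (largest
component, holes filled), centroids tracked in µm, and instantaneous speed
computed frame-to-frame, boxcar-smoothed over five frames, then averaged
over the condition's time window. The estimator has a positive noise
floor: a stationary cell with isotropic Gaussian tracking noise σ yields
an expected speed of $\sigma\sqrt{\pi}/\Delta t$, which the tests verify
in closed form. Displacement angles run from the mean of the first three
to the mean of the last three centroids, measured against the gradient
axis; zero net displacement is excluded (and counted), not coerced to 0.
Angular precision is the mean resultant length
$p = \sqrt{(\overline{\sin\theta})^2 + (\overline{\cos\theta})^2}$, with a
seeded 1000-replicate bootstrap; the point estimate on the original sample
is primary and the bootstrap s.d. is the reported uncertainty (the source
procedure does not name the bootstrap summary, so this is the package's
choice). Concentration recovery inverts $I_1(\kappa)/I_0(\kappa) = p$ with
Fisher's small-sample correction (`estimate_kappa()`), without which
$\hat\kappa$ is noticeably inflated at $n \approx 18$.

Morphodynamic maps resample each frame's contour to equal arc length
counter-clockwise from the gradient direction and assign each contour
point the signed distance to the next frame's boundary (difference of the
two frames' signed distance-transform fields, evaluated at the same
sub-pixel points, which cancels the half-pixel discretization bias of a
single distance transform) divided by the frame interval. Rows are ordered
so contour coordinate 0 (the gradient direction) sits mid-map. Signed
distance differencing was chosen over normal-projection point matching
because it is robust to contour resampling drift. The maps satisfy a
Green's-theorem consistency check (mean edge velocity × perimeter ≈ area
change rate, within 5% for smooth masks), and directed-migration movies
show the protrusive band at coordinate 0 with retraction at ±π.

## Numerical choices and problem sizes

Grids default to 0.05 µm spacing over 0–35 µm (profile ensembles use the
0.25 µm pixel grid over a 20 µm window). The brute-force oracle for the
bump position uses a 0.005 µm grid. Recovery statistics run 200 seeded
replicates per estimate; rank-sum calibration uses 1000 seeded repeats at
~200 positions; migration recovery uses 18-cell ensembles (movies for the
speed pipeline, ground-truth tracks for concentration replicates). All
generators accept explicit seeds and reproduce bit-identical output under
a fixed seed. These sizes were chosen so each check constrains its
estimate well below the tolerance it is compared against.

## Known limitations

* The model is strictly steady-state: no excitable dynamics, pulses, or
  pattern evolution (deliberately out of scope), and no spatial transport
  term.
* Amplitudes are arbitrary units end to end; only ratios and length
  scales are meaningful.
* The 20 µm measurement window and the plateau reading of the Cdc42 shape
  are calibrated interpretations of summary statistics whose acquisition
  window is not reported; both are configurable.
* Real-data entry points (TIFF + JSON sidecar, CSV tables) assume
  registered, flat-field-corrected channels and externally supplied
  linescan geometry; no automatic detection of protrusive regions is
  attempted.
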