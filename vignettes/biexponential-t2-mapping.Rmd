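---
title: "Biexponential T2 mapping: model, reconstruction and group analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biexponential T2 mapping: model, reconstruction and group analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biexpT2)
```

## The signal model

Many soft tissues of the stomatognathic system (the temporomandibular
disk, retrodiscal tissue, condylar bone marrow, masticatory muscles,
dental pulp) contain more than one water compartment, so their transverse
magnetization does not decay as a single exponential. `biexpT2` models the
magnitude signal of a voxel measured at echo time $TE$ as a two-pool sum

$$ S(TE) \;=\; A_s\, e^{-TE/T_{2s}} \;+\; A_l\, e^{-TE/T_{2l}}, $$

with a short component $(A_s, T_{2s})$ and a long component
$(A_l, T_{2l})$; all times are in milliseconds, amplitudes in arbitrary
scanner units. The *fractions* are each amplitude's share of the total,
$f_s = A_s/(A_s+A_l)$ and $f_l = 1-f_s$; they sum to one exactly. The
monoexponential model $S(TE) = A\,e^{-TE/T_2}$ is the single-pool special
case and is always fitted alongside for model-adequacy assessment.

The default echo grid is the eight-echo turbo-spin-echo protocol
$TE \in \{13, 26, \dots, 104\}$ ms. Three or more pools are out of scope.

## Weighted voxelwise fitting

Each voxel is fitted independently — no spatial smoothing or coupling of
any kind, so boundaries of uniform regions are preserved by construction.
The objective is a weighted mean squared error,

$$ \mathrm{MSE}(\theta) = \frac{1}{n}\sum_{i=1}^{n} w_i\,
   \bigl(S_i^{\mathrm{obs}} - S(TE_i;\theta)\bigr)^2 , $$

where the echo weights compensate for echo-to-echo differences in noise
level: $w_i \propto 1/\sigma_i^2$, normalized to mean one.
`estimate_weights()` accepts known per-echo noise SDs or estimates them
from a background region (at least 20 voxels per echo; a constant
background is rejected because its variance carries no information).

Minimization uses Powell's conjugate-direction method
(`powell_minimize()`): a derivative-free direction-set scheme that cycles
over an evolving set of search directions, line-minimizing along each with
golden-section bracketing followed by Brent parabolic interpolation, and
replaces the direction of largest single decrease by the cycle's net
displacement when the standard extrapolation test accepts it. Stopping is
by fractional function decrease per cycle (`ftol`), parameter change
(`xtol`) or a cycle cap. A derivative-free method is deliberate: the
clipped parameter bounds make the objective only piecewise smooth.

Numerical choices that matter:

* **Bounds.** $T_2 \in (0.01, 2000]$ ms, enforced by clipping inside the
  objective; amplitudes are clipped at zero. The echo grid is sensitive to
  roughly 5–500 ms, so the upper bound is generous rather than
  informative.
* **Initialization and restarts.** Biexponential least squares is
  multi-modal, so the fit is multi-start: a primary seed from a
  two-segment log-linear split (the last three echoes estimate the long
  component, the residual of the first three the short one) plus four
  deterministic starts on a coarse $(T_{2s}, T_{2l})$ lattice
  $\{10,35\} \times \{90,200\}$ ms, with start amplitudes solved by
  weighted linear least squares at the fixed time constants. The best
  restart by objective value wins; a restart that reaches a numerically
  exact fit short-circuits the rest.
* **Ordering.** $T_{2s} \le T_{2l}$ is imposed by a post-fit swap that
  carries the amplitudes along, keeping the search space smooth.
* **Reduced problem.** `fit_biexp(..., amp_total = )` solves the
  three-parameter problem $(f_s, T_{2s}, T_{2l})$ with the amplitude sum
  fixed, for settings where the $TE\!=\!0$ signal is known — e.g.
  normalized synthetic phantoms, where it removes the amplitude/T2
  trade-off that dominates estimator variance.

## Degeneracy classification

A biexponential fit is only kept where it is meaningfully biexponential.
A voxel is classified monoexponential when **any** of these rules fires
(a pure logical OR, so rule order is irrelevant):

1. a relaxation-time component is numerically zero ($< 0.01$ ms — exact
   zeros are measure-zero in floating point, so "zero" needs a tolerance);
2. the two time components differ by less than 1 ms;
3. an amplitude is numerically zero ($< 10^{-6}$ of the amplitude sum);
4. the monoexponential fit has a strictly lower weighted MSE.

Rule 4 uses raw MSE with no degrees-of-freedom penalty: since the mono
model is nested in the biexponential one, a lower mono MSE is possible
only through the constraint boundary or optimizer imperfection — which is
precisely the degeneracy signal the rule encodes. Classified-out voxels
carry `NA` sentinels in every biexponential map, are `FALSE` in the
validity mask, and are excluded from all ROI statistics; exclusion can
only shrink an ROI's n, never contaminate its mean.

## The synthetic phantom and cohort generator

The study's clinical scans are not publicly deposited, so the package
generates its own data with the statistical structure the analysis
assumes. `tissue_reference()` carries the across-study means and SDs of
$T_{2s}$, $T_{2l}$ and $f_s$ for seven structures in two groups (disk
displacement, $n=18$; no displacement, $n=32$).

* `sample_voxel_params()` draws $T_2$ values from truncated normals
  (lower bound 1 ms, resampling until $T_{2s} < T_{2l}$) and $f_s$
  truncated to $(0.01, 0.99)$; amplitudes are $(f_s, 1-f_s)$ so each
  voxel's amplitude sum is one and amplitudes are directly fractions —
  the reference tables report fractions, not raw scanner amplitudes.
  The printed short and long fraction means of the reference table do not
  always sum to one (the pulp row is internally inconsistent); the
  generator does not attempt to reproduce that inconsistency and always
  uses $f_l = 1 - f_s$, which the fraction definition forces per voxel.
* `make_phantom()` places rectangular, non-overlapping ROIs on a small
  grid (default $32\times32\times1$ — matrix size does not change
  per-voxel physics, and desk-scale grids keep tests fast; the grid is
  configurable), evaluates the closed-form decay per voxel and records
  truth maps. Background voxels are zero before noise.
* `add_noise()` is Gaussian per echo by default (a valid high-SNR
  approximation for magnitude data); Rician noise — the magnitude of both
  noisy quadratures — is available via `model = "rician"`.
* `make_cohort()` draws one ROI-mean parameter set per subject per
  structure, with subject-to-subject scatter given by the across-study SD
  columns. Within-ROI voxel scatter is separate and defaults to zero,
  because the reference tables say nothing about voxelwise spread.

All randomness flows through explicit seeds; identical seeds give
byte-identical phantoms, cohorts and noise.

What the generator does **not** emulate: anatomically realistic TMJ
geometry, partial-volume mixing at ROI boundaries, $B_1$ and
stimulated-echo artifacts of turbo-spin-echo trains, spatially correlated
noise, or scanner drift. Tests that pass on these phantoms therefore
validate the estimator and the statistics pipeline, not robustness to
those acquisition effects.

## ROI statistics

`roi_summary()` averages a map over the valid in-mask voxels.
`average_segmentations()` handles repeated manual segmentation by
averaging the two masks' ROI means (and SDs) — the most literal reading of
analysing "the average of two measurements" — rather than unioning masks.
Group comparisons (`group_analysis()`) use the classical pooled-variance
two-sample t-test on subject-level ROI means, $df = n_A + n_B - 2$:
recomputing the retrodiscal short-$T_2$ reference row from its printed
summaries gives $p = 7.6\times10^{-5}$ under pooling, consistent with the
printed value, whereas Welch gives $\approx 8\times10^{-4}$; Welch remains
available behind `welch = TRUE`. Significance is Bonferroni-corrected
with $m = 4$ (the four components per structure), $0.05/4 = 0.0125$, and
$0.0125 \le p < 0.05$ is flagged as a trend. Normality is checked per
group with Shapiro–Wilk. Pearson correlations (with the $t$-transform
p-value), Cohen's $\kappa$ for two raters, and intersection-over-union
for repeated segmentations round out the reliability toolkit. Left and
right joints of one patient are treated as independent observations, as
in the underlying study design; no mixed-effects correction is applied.

Zero-variance groups use the limit convention $p=1$ for equal means and
$p=0$ otherwise.

## Problem sizes used by the test and acceptance runs

Noiseless recovery phantoms use a $5\times5$ grid with a 16–25-voxel ROI
(every zero-SD voxel is identical, so a handful suffice); noisy recovery
uses 500-voxel ROIs at $\sigma = 1\%$ of the first-echo signal; the
optimizer-versus-grid-oracle check uses 100 random noiseless curves
against a $60\times49\times19$ lattice; the type-I-error simulation runs
200 null cohorts and the power simulation 100 cohorts at $n = 18/32$.
These sizes were chosen as the smallest that make the Monte-Carlo
standard errors comfortably smaller than the margins being checked.

## Known limitations

* **Long-$T_2$ estimation near and beyond the echo window.** With
  $TE \le 104$ ms, time constants around 100–150 ms are covered by barely
  one decay constant. At an SNR of 100 the unconstrained four-parameter
  estimator of $T_{2l}$ has a heavy right tail (occasionally running to
  the 2000 ms bound), so voxelwise ROI *means* of $T_{2l}$ can sit far
  above the generative value even when the median is close. This is
  estimator variance, not an optimizer defect: independent nonlinear
  least-squares fits started at the truth land on the same minima. The
  reduced three-parameter fit shrinks but does not remove the effect.
  Short-$T_2$ maps, which the echo grid samples well, do not show it.
* The degeneracy rules are threshold-based and make no multiple-testing
  adjustment across voxels.
* Monoexponential and biexponential fits share the weighting; no
  Rician-bias correction is applied to either (relevant only at low SNR).
* The pulp reference row's internal inconsistency (see above) means
  synthetic pulp fraction contrasts between groups are driven by the
  printed short-fraction means as given and should not be
  over-interpreted.
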