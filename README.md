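# biexpT2

Voxelwise biexponential T2 relaxometry for multi-echo magnitude MRI, with
a synthetic phantom/cohort simulator and two-group ROI statistics. The
package targets quantitative studies of the stomatognathic system — the
temporomandibular disk, retrodiscal tissue, condylar bone marrow,
masticatory muscles and dental pulp — where tissues hold several water
compartments and a single-exponential T2 map is inadequate, but it applies
to any multi-echo T2 decay data.

## The model and the method

The magnitude signal of a voxel at echo time `TE` is modeled as a
two-pool decay

    S(TE) = A_s * exp(-TE / T2s) + A_l * exp(-TE / T2l)

with a short component `(A_s, T2s)` and a long component `(A_l, T2l)`;
the short/long *fractions* are `f_s = A_s / (A_s + A_l)` and
`f_l = 1 - f_s`. Each voxel is fitted independently by minimizing an
inverse-variance-weighted mean squared error with Powell's
conjugate-direction method (derivative-free, multi-start), alongside a
monoexponential fit `S(TE) = A * exp(-TE / T2)`. A voxel is classified
monoexponential — and excluded from all biexponential maps and ROI
statistics — when a time component is numerically zero, the two time
components differ by less than 1 ms, an amplitude is numerically zero,
or the monoexponential fit achieves a lower weighted MSE. The surviving
voxels form short/long T2 maps, amplitude maps, fraction maps and a
validity mask.

ROI-level group comparisons use classical pooled-variance two-sample
t-tests on subject-level ROI means with Bonferroni correction
(`0.05 / 4 = 0.0125` for the four components of a structure),
Shapiro–Wilk normality checks, Pearson correlations, Cohen's kappa and
intersection-over-union reliability measures.

Because the underlying clinical scans are not publicly deposited, the
package ships a generator for synthetic multi-echo phantoms and two-group
cohorts (18 disk-displacement vs. 32 no-displacement joints)
parameterized by published reference means and SDs for seven structures
(`tissue_reference()`).

## Worked example

Fit the reference retrodiscal-tissue decay (no-displacement row:
`T2s = 17.6` ms, `T2l = 105.3` ms, `f_s = 0.666`) on the standard
eight-echo grid:

```r
library(biexpT2)

tes <- default_echo_times()            # 13, 26, ..., 104 ms
truth <- biexp_params(amp_short = 0.666, amp_long = 0.334,
                      t2_short = 17.6, t2_long = 105.3)
signal <- biexp_signal(truth, tes)
round(signal, 4)
#> [1] 0.6134 0.4129 0.3033 0.2385 0.1967 0.1672 0.1445 0.1262

fit <- fit_biexp(signal, tes)
str(fit$params)
#> List of 4
#>  $ amp_short: num 0.666
#>  $ amp_long : num 0.334
#>  $ t2_short : num 17.6
#>  $ t2_long  : num 105
```

The fit recovers the generating parameters to machine-level accuracy; on
a noiseless curve the short component 17.6 ms, the long component
105.3 ms and the short fraction 0.666 are reproduced exactly. The group
contrast for the same structure, computed from the published per-group
summaries (mean, SD, n of the short T2 in each group):

```r
unlist(pooled_t_test(22.6, 5.2, 18, 17.6, 3.0, 32))
#>            t           df            p
#> 4.326022e+00 4.800000e+01 7.648057e-05

bonferroni_alpha(0.05, 4)
#> [1] 0.0125
```

so the retrodiscal short-T2 difference between displacement groups is
significant well below the Bonferroni-corrected threshold.

## The analysis workflow

The `analysis/` scripts run the full study pipeline on synthetic data and
write their tables and maps under `results/`:

1. `analysis/01_simulate.R` — two-group cohort (CSV) and noiseless/noisy
   single-ROI phantoms (NIfTI + JSON sidecars with echo times and seeds).
2. `analysis/02_reconstruct.R` — voxelwise reconstruction of both
   phantoms into T2/amplitude/fraction map stacks with validity masks.
3. `analysis/03_analyze.R` — the 7-structure × 4-component group
   comparison grid with Bonferroni significance and trend flags.
4. `analysis/04_report.R` — mono- vs. biexponential model-adequacy
   report: fitted curves over the eight echoes and the voxelwise MSE
   ratio (the monoexponential fit's error is typically tens of times
   higher in biexponential tissue).

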