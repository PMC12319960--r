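# chisep

Paramagnetic/diamagnetic susceptibility source separation for multi-echo
gradient-echo (GRE) MRI, with a ground-truth digital phantom and exact
nonparametric group statistics.

## The problem

Quantitative susceptibility mapping (QSM) reports one bulk susceptibility
per voxel. Where paramagnetic sources (iron-laden microglia, ferritin) and
diamagnetic sources (protein aggregates such as hyperphosphorylated tau,
myelin) co-localize, their opposing phase contributions cancel and bulk QSM
under-reports both — the pathologies of interest in neurodegeneration are
exactly of this co-localizing kind. `chisep` fits the multi-echo complex
signal to a three-pool model and reports the paramagnetic and diamagnetic
component susceptibilities (PCS, DCS) separately, plus the statistics needed
for small-cohort group comparisons.

## The model

Each voxel mixes a neutral, a paramagnetic (χ₊ ≥ 0) and a diamagnetic
(χ₋ ≤ 0) pool:

    S(t) = α₀ e^(−R₂₀* t)
         + α₊ e^(−(R₂₀* + a χ₊) t) e^(+i (2/3) γ B₀ χ₊ t)
         + α₋ e^(−(R₂₀* − a χ₋) t) e^(+i (2/3) γ B₀ χ₋ t)

with the static-dephasing decay kernel a = 2π γ B₀ / (9√3) for spherical
sources (1.26 kHz/ppm at 11.7 T) and the Lorentz sphere factor 2/3 in the
phase. Both χ-pools decay *faster* than the neutral pool; the magnitude
carries |χ|, the phase its sign. The fit is a constrained three-step
alternating minimization (exact NNLS for the amplitudes; bounded
trust-region solves for R₂₀* and (χ₊, χ₋) on the amplitude-profiled
objective), run from a data-driven and a matrix-pencil start. Composite
maps are PCS = C₊χ₊ and DCS = C₋χ₋ with C the signal fractions normalized
to sum to one.

The full pipeline: Laplacian phase unwrapping → V-SHARP background removal
(spherical mean value kernels, radii 25→1 voxels) → thresholded k-space
dipole inversion (per-echo χ(t) and multi-echo combined, referenced to the
whole-brain mean) → three-pool fit → exact Mann–Whitney U (complete
enumeration) with Benjamini–Hochberg FDR across ROIs.

## Worked example

Simulate a phantom at the default acquisition (11.7 T, 8 echoes,
TE₁ = 4 ms, ΔTE = 3.8 ms), run the QSM chain, and summarize ROIs:

```r
library(chisep)
params <- acq_params()
params
#> <acq_params> B0 = 11.7 T, 8 echoes (4.0..30.6 ms), voxel 0.07x0.07x0.07 mm
signif(decay_kernel(params$B0)$a_khz_per_ppm, 3)
#> [1] 1.26

sim <- simulate_phantom(grid_shape = c(32, 32, 32), layout = "shells",
                        seed = 1, mode = "field", snr = 40)
u  <- laplacian_unwrap(sim$series$phase, sim$truth$mask$mask)
f  <- combine_echoes(u, params)           # normalized field, ppm
lf <- vsharp(f, sim$truth$mask$mask, max_radius_vox = 25)
q  <- combined_qsm(lf$field, params, delta = 0.2, mask = lf$eroded_mask)

tm <- truth_maps(sim$truth)
cor(q$chi[lf$eroded_mask], tm$chi_bulk[lf$eroded_mask])
#> [1] 0.8046142   # noisy 32^3 example; 0.952 noiseless at 48^3

roi_means(to_ppb(q$chi), sim$truth$labels)
#>  label         name n_voxels       mean       sd
#>      1 neutral_core      296 -0.1792894 1.495905
#>      2 paramagnetic     1056  5.4022917 1.890528
#>      3  diamagnetic     2352 -3.5336179 2.129307
#>      4        mixed     3696  0.3971960 1.879338
#>      5  neutral_rim     3528  0.3376652 1.146038
```

The paramagnetic shell (true bulk +7 ppb) and diamagnetic shell (−4.5 ppb)
are recovered with the expected TKD amplitude scaling; the mixed shell,
whose χ₊ and χ₋ nearly cancel, sits near zero in bulk QSM — separating it
is the three-pool fitter's job (`fit_three_pool_volume`).

Group comparison on a simulated 5-vs-5 cohort with a lesion effect:

```r
tab <- simulate_cohort(n_per_group = 5, seed = 7)
res <- compare_groups(tab, metric = "PCS", q = 0.05)
res[, c("roi", "mean_A", "mean_B", "U", "p", "p_fdr", "significant")]
#>           roi  mean_A  mean_B  U       p  p_fdr significant
#>  neutral_core -0.2951  0.1420  5 0.15079 0.4524       FALSE
#>  paramagnetic  7.3686  7.4237 10 0.69048 1.0000       FALSE
#>   diamagnetic  0.0469  0.1044 12 1.00000 1.0000       FALSE
#>         mixed  3.1078  3.0704 13 1.00000 1.0000       FALSE
#>   neutral_rim  0.2838  0.0762 17 0.42063 0.8413       FALSE
#>        lesion  2.1356 10.1902  0 0.00794 0.0476        TRUE
```

The lesion ROI (PCS 2.1 vs 10.2 ppb) is flagged at p = 2/252 = 0.0079 —
the smallest exact two-sided p attainable with n = 5 per group — and
survives FDR correction; the null ROIs do not.

A command-line interface covers the same stages
(`inst/scripts/chisep simulate|unwrap|vsharp|combine-echoes|qsm|decompose|roi-stats`).

## Scope notes

Dipole inversion is thresholded k-space division (plus an optional
closed-form Tikhonov variant), a documented stand-in for iterative
streak-suppressing solvers. PCS/DCS are defined as the fraction-weighted
component susceptibilities. At realistic SNR the χ₊/χ₋ *point estimates*
have an identifiability ceiling (the composites are the robust outputs);
see the methods vignette (`vignettes/susceptibility-source-separation.Rmd`)
for the analysis, all tunable parameters, and known limitations.
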