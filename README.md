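# fwetract

Free-water elimination tractometry for single-shell diffusion MRI, built as a
fully simulation-driven R package.

## The problem

Diffusion tensor imaging (DTI) summarizes water diffusion in each voxel of a
white-matter bundle by a 3×3 tensor and its scalars — fractional anisotropy
(FA), mean/radial/axial diffusivity (MD, RD, AD). In aging brains these
measures are contaminated by partial-volume free water (CSF and enlarged
interstitial space), which inflates diffusivities and depresses FA. Free-water
elimination (FWE) fits a two-compartment **bi-tensor** model per voxel,

    S(b, g) = S0 · [ (1 − f) · exp(−b gᵀ D g) + f · exp(−b d_iso) ],

with a tissue tensor `D`, a free-water volume fraction `f ∈ [0, 1]`, and a
fixed isotropic diffusivity `d_iso = 3·10⁻³ mm²/s` (water at body
temperature). The tissue-only scalars (FAt, MDt, RDt, ADt) and the free-water
map `f` are then related to longitudinal cognitive decline — subject-specific
verbal-fluency slopes over 12 years estimated by a linear mixed model —
through covariate-adjusted standardized-β regressions under
Benjamini–Hochberg FDR control.

Cohort imaging data of this kind are not public, so every input here is
synthetic with planted ground truth: single-shell acquisition schemes (1–2 b0
plus 21 directions and their antipodes per series at b = 1000 s/mm²),
bundle-shaped phantoms with white-matter-hyperintensity (WMH) overlap and
Rician noise, screening tables with staged exclusions (239 screened → 68
included), and nested Isaacs-Set-Test trajectories. Recovery of the planted
truth is the package's acceptance surface. The audience is methods developers
and students who want an end-to-end, testable FWE pipeline at desk scale.

## Worked example

Simulate one contaminated voxel at the cohort-mean operating point (tissue
FA 0.567, MD 0.755·10⁻³ mm²/s, free-water fraction 0.141, SNR 20), fit both
models, and compare:

```r
library(fwetract)

scheme <- make_gradient_scheme(21, 1000, 2)   # 87 volumes, 3 b0, 84 DW
ev  <- tensor_from_scalars(0.567, 0.755e-3)
vox <- voxel_model(tensor_from_eigen(ev, axis = c(0, 1, 0)), fw_fraction = 0.141)
sig <- simulate_bitensor_signal(vox, scheme, snr = 20, seed = 7)

fit_single_tensor(sig, scheme)
#> tensor_fit: FA 0.4867  MD 0.000876 mm^2/s
fit_bitensor(sig, scheme)
#> free_water_fit: f 0.1159  FAt 0.5439  MDt 0.0007631 mm^2/s
```

The conventional fit is biased exactly as expected under contamination (FA
pulled down from 0.567 to 0.49, MD inflated from 0.755·10⁻³ to 0.88·10⁻³);
the bi-tensor fit recovers the planted tissue values and the free-water
fraction to within the noise. On noise-free signals the recovery is exact to
about seven digits.

Association layer on a synthetic 68-subject cohort with a planted
standardized effect β = −0.4 of MDt on the IST15 slope:

```r
co <- simulate_association_cohort(n = 68, beta_mdt = -0.4, seed = 1)
t3 <- table_regressions(co)
subset(t3, family == "fw_corrected" & slope == "slope_ist15")
#>  measure   beta r_squared    p_fdr significant
#>      fat  0.083     0.030 0.636          FALSE
#>      mdt -0.411     0.190 0.0042          TRUE
#>      adt -0.311     0.119 0.0257          TRUE
#>      rdt -0.365     0.156 0.0088          TRUE
#>       fw  0.066     0.027 0.636          FALSE
```

The planted MDt effect is recovered (β = −0.41) and survives FDR at q = 0.05,
with the correlated diffusivities inheriting attenuated effects.

The full chain — phantoms → tensor and free-water maps (NIfTI) → bundle
tract summaries → mixed-model slopes → comparison and regression tables —
runs from one config:

```r
cfg <- pipeline_config(n_subjects = 12, shape = c(16, 16, 10), seed = 42)
run_pipeline(cfg)   # writes CSV tables + manifest under cfg$out_dir
```

or from the shell via `Rscript inst/cli/fwetract.R run-all --seed 42 --out run/`.

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch against the installed
package, the recovery targets the test suite also checks: the bi-tensor fit's
tissue FA, MD, AD and RD on noise-free signals simulated at the cohort-mean
operating point, and the mixed-model fixed-effect annual slope on a
2000-subject synthetic verbal-fluency cohort. Run it as

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It writes one JSON object with a numeric `value` and problem size `n` per
target.
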