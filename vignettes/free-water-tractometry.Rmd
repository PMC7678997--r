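---
title: "Free-water elimination tractometry: models, estimators, and the synthetic world"
author: "fwetract"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-water elimination tractometry: models, estimators, and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fwetract)
```

## The model

Each voxel's diffusion-weighted signal on a single shell is modeled as a
two-compartment mixture,

$$S(b, \mathbf{g}) = S_0\left[(1 - f)\,e^{-b\,\mathbf{g}^\top D\,\mathbf{g}} + f\,e^{-b\,d_{iso}}\right],$$

where $D$ is the symmetric positive semi-definite tissue tensor (mm²/s), $f$
the free-water volume fraction, and $d_{iso} = 3\times10^{-3}$ mm²/s the
diffusivity of free water at body temperature, held fixed. Conventional DTI
fits a single tensor to the same data and therefore reports a
signal-fraction-weighted blend of both compartments; its scalars (FA, MD, RD,
AD) are biased toward isotropy and higher diffusivity wherever $f > 0$.
Removing the free-water compartment yields tissue scalars FAt, MDt, RDt, ADt
and the free-water map itself.

Assumptions worth stating: the free-water compartment is perfectly isotropic
with a known diffusivity; there is no exchange between compartments; the
tissue compartment is a single Gaussian tensor (no crossing-fiber or
kurtosis terms); noise is Rician, as for magnitude MRI.

## Estimators

**Conventional tensor** (`fit_single_tensor`). Weighted log-linear least
squares: an OLS pass on $\ln S$ followed by one refinement with weights equal
to the squared predicted signal — the standard WLS estimator, deterministic
and iteration-free. $S_0$ is the exponentiated intercept, estimated jointly
so that multiple b0 volumes are treated consistently. Negative eigenvalues
are clamped to zero and flagged rather than rejecting the voxel, preserving
map completeness while keeping a QC trail. On noise-free data the inversion
is exact (tested to 1e-9 relative).

**Bi-tensor fit** (`fit_bitensor`). Bounded nonlinear least squares over
$(S_0, f, L)$ with $D = LL^\top$ parameterized by its lower-triangular
square-root factor, so positive semi-definiteness is structural rather than
constrained. Internally diffusivities are scaled by $10^3$ and b-values by
$10^{-3}$ so every optimizer coordinate is order one. Optimization uses
L-BFGS-B with analytic gradients, box bounds $f \in [0, 1]$, a relative cost
tolerance of 1e-10, a 500-iteration cap, and one polishing restart. The cost
is multiplied by a large constant ($10^6$) before optimization: L-BFGS-B's
stopping rule measures progress relative to $\max(|cost|, 1)$, and a
noise-free minimum approaching zero would otherwise allow the line search to
stop while parameters are still a few percent off. The lower bound on $f$ is
0 (not a small positive floor): a planted $f = 0$ voxel must reproduce the
conventional fit exactly, and the box bound causes no gradient pathology.

**Initialization.** $f$ starts at the linear interpolation of the
conventional MD between a typical tissue diffusivity
($0.6\times10^{-3}$ mm²/s, initialization only, never a constraint) and
$d_{iso}$, clamped to $[0.01, 0.99]$; the tissue tensor starts at the
free-water-corrected conventional tensor projected onto the SPD cone.

**Single-shell identifiability and the noise-scaled prior.** With one nonzero
shell the decomposition "exponential-quadratic plus constant" is unique on
exact data, but the likelihood valley trading $f$ against tissue diffusivity
is extremely shallow: profiling the cost over $f$ on this package's 87-volume
scheme gives a curvature of roughly $1.3\times10^{-4}$ (normalized units)
against a noise floor of about $0.16$ at SNR 20. An unpenalized per-voxel
minimizer therefore wanders along the valley under noise (empirically a
bimodal $f$ near 0 or 0.45 for a true 0.141). This is the well-known reason
single-shell free-water estimation is regularized. The package's estimator
adds an empirical-Bayes penalty

$$\frac{\hat\sigma^2}{\tau^2}\,(f - f_{init})^2,$$

with $\hat\sigma^2$ the per-volume residual variance of a first, unpenalized
pass and $\tau = 0.1$ the stated prior uncertainty of the MD-interpolation
initialization. The penalty is proportional to the noise level: on noise-free
data it vanishes (machine-zero residuals) and the estimator is exact maximum
likelihood, which is what the recovery contracts exercise; on noisy data it
dominates the flat valley and the estimator inherits the interpolation
initialization's small bias (measured: median $f$ 0.121 for a truth of 0.141,
RMSE 0.024 at SNR 20 over 500 voxels) instead of the valley's arbitrary
scatter. $\tau$ was chosen once, before measuring, as a realistic uncertainty
for an MD-based $f$ guess in white matter; `f_prior_sd = Inf` disables the
penalty. An optional outer loop (`fit_fw_volume(smooth_sigma = 1)`) Gaussian-
smooths the $f$ map between refits as a light surrogate for spatial
regularization; it is off by default so the per-voxel estimator remains
exactly testable.

**Degeneracy.** When the fitted tissue tensor is nearly isotropic
(FAt < 0.05) the tissue and free-water compartments are not distinguishable
on a single shell; such voxels are flagged, not dropped.

## The synthetic world

The phantom (`make_phantom`) states the cohort's reported operating point as
its defaults: bundle tissue FA 0.567 and MD $0.755\times10^{-3}$ mm²/s (the
corrected cingulum means), free-water fraction drawn around 0.141 (SD 0.03),
WMH covering 3.2% of the bundle, 2 mm isotropic voxels, and the acquisition
layout of one b0 + 21 directions + 21 antipodes per series, two series (the
second with two b0 volumes), b = 1000 s/mm². Geometry is deliberately
simple — two parasagittal tubes inside a white-matter slab inside an
intracranial box — because the out-of-scope stages (tractography, lesion
segmentation) are replaced by their mask outputs. WMH voxels get a more
isotropic, more diffusive tissue tensor and +0.1 free water; non-WM
intracranial voxels are CSF-like ($f = 0.9$). The half-sphere directions are
a Fibonacci-hemisphere layout refined by a fixed number of
electrostatic-repulsion steps: fully deterministic (no RNG), which is
strictly stronger than the "fixed internal seed" a seeded layout would give.

What the phantom does **not** emulate: eddy currents, motion, susceptibility
distortion, realistic anatomy, crossing fibers, streamline geometry, or
multi-shell sampling. A green recovery test therefore establishes estimator
correctness under the stated forward model, not robustness to acquisition
artifacts.

The longitudinal generator (`simulate_longitudinal_scores`) writes the
reported 12-year decline into its defaults: visits at 0/2/4/7/10/12 years and
mean annual slopes −0.489 / −0.697 / −0.924 words/year for the 15/30/60 s
scores. The three scores are cumulative counts of one fluency trial, so they
are generated as the 15 s trajectory plus two non-negative increments, which
enforces IST15 ≤ IST30 ≤ IST60 at every visit by construction. Increment
intercepts default to 10 words each (a baseline of 18/28/38 words, a
realistic elderly profile; the cohort's baseline levels are not reported) and
increment random effects scale from the main arguments (factors 0.3/0.5) so
the deterministic limit stays deterministic. Truncation at zero words can in
principle bend extreme trajectories; planted slopes are recorded
pre-truncation.

The screening generator plants the staged attrition 8, 27, 62, 24, 15, 16, 19
on disjoint subject sets of 239 records, with optional redundant later flags
on already-excluded subjects; `apply_exclusions` attributes each subject to
the first failing stage, the only order under which the printed counts sum to
the 68 included. The stage order is the order the stages are reported in.

The table-level cohort generator (`simulate_association_cohort`) drives the
error-control simulations without imaging: measures follow the reported means
and SDs with a two-factor (tissue state, contamination) correlation
structure, and a standardized effect `beta_mdt` of MDt on the IST15 slope is
planted directly, so `beta_mdt = 0` is an exact null.

## Statistics

Standardized-β regressions z-score the outcome and the predictors of
interest, entering covariates raw, which reproduces the "standardized
coefficient adjusted for ..." convention; for a single predictor without
covariates β equals the Pearson correlation (tested to 1e-12). Adjustment
covariates are age and the cingulum bundle volume as % of intracranial volume
(the %TIV convention of the cohort's descriptive table; configurable), with
the WM-normalized log-transformed WMH burden as an optional addition. The
WMH log transform uses the natural log with one voxel volume over the WM
volume added inside the log so lesion-free subjects stay finite. FDR families
follow presentation granularity: one family per results table block
(conventional measures × scores; corrected measures + FW × scores; the four
paired comparisons). All tests are two-sided. Spearman p-values are exact
(no ties, n ≤ 10) or t-approximate; Mann-Whitney is exact below group size 20
without ties, else normal with continuity and tie correction.

Subject slopes are REML mixed-model BLUPs (`lme4::lmer`, correlated random
intercept and slope); a singular correlated fit falls back to independent
random effects and is flagged; per-subject OLS slopes are emitted alongside
as the two-stage cross-check. lme4 replaces the hand-rolled profile-likelihood
optimizer a first design sketch called for: it is the field-standard
estimator, deterministic given data, and exposes exactly the contracts needed
(REML, BLUPs, singularity detection).

## Numerical choices and edge cases

* Tensor eigenvalue clamp at 0 with a `clamped` flag; FA undefined (error)
  only for an all-zero tensor.
* `tensor_from_scalars` uses the prolate branch: with
  $a = \mathrm{FA}/\sqrt{3 - 2\,\mathrm{FA}^2}$, eigenvalues are
  $\mathrm{MD}(1+2a)$ and $\mathrm{MD}(1-a)$ twice — the unique axially
  symmetric cigar-shaped solution.
* Rician noise: the noise-free value is the real channel; both quadrature
  channels receive $N(0, \sigma^2)$, $\sigma = S_0/\mathrm{SNR}$.
* Identical paired vectors return t = 0, p = 1 (no evidence); a nonzero
  constant difference (undefined t) raises a degenerate-test error.
* Pipeline covariates with zero variance (e.g. identical phantom geometry
  across subjects) are dropped from the adjustment set rather than producing
  a collinear design; cohorts below 8 subjects run unadjusted models, and
  below 10 subjects slopes fall back to per-subject OLS.
* All pipeline randomness derives from one master seed (subject parameters,
  phantoms, scores, screening each get fixed offsets); the manifest records
  the seed, package version, and per-stage wall time.

## Limitations

The free-water compartment of real tissue need not be perfectly isotropic,
and the bi-tensor model shares the single-tensor model's blindness to
crossing fibers. Tract means here are unweighted over mask voxels, a
documented divergence from streamline-based aggregation (the tractography
stage is out of scope). Noisy free-water estimates inherit the
initialization's small negative bias by design — the honest price of
single-shell data; multi-shell acquisition would remove the degeneracy
rather than regularize it.
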