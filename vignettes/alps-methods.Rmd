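---
title: "Methods: DTI-ALPS indices, synthetic cohorts, and subgrouping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DTI-ALPS indices, synthetic cohorts, and subgrouping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpsindex)
```

## The model

Diffusion-weighted MRI measures signal attenuation
$S = S_0 \exp(-b\, g^\top D g)$, where $b$ (s/mm²) is the diffusion
weighting, $g$ a unit gradient direction and $D$ the voxel's symmetric
diffusion tensor (mm²/s). `alpsindex` fits $D$ per voxel by the
log-linearized least-squares system
$\log S = \log S_0 - b\, g^\top D g$, either ordinary (OLS) or with one
reweighting pass using squared predicted signals as weights (WLS, the
default). Both are closed-form; on noise-free monoexponential data they
are identical and exact, which is what makes the phantom pipeline an
exact end-to-end check rather than an approximate one.

The DTI-ALPS index reads four diagonal entries of the fitted tensors at
the level of the lateral-ventricle body, where perivascular spaces of
the medullary veins run along the image x-axis while the neighboring
projection and association fiber tracts run along z and y:

$$\mathrm{ALPS} = \frac{\mathrm{mean}(D_{xx}^{\text{proj}},
D_{xx}^{\text{assoc}})}{\mathrm{mean}(D_{yy}^{\text{proj}},
D_{zz}^{\text{assoc}})}$$

Each quantity is the arithmetic mean of a 3×3-voxel square ROI on a
single axial slice (≈5.4 mm at 1.8 mm in-plane resolution). The ratio
is dimensionless and scale-invariant; values near 1 indicate that
x-diffusivity is no higher than fiber-perpendicular diffusivity
elsewhere, i.e. impaired perivascular flow, while healthy values are
roughly 1.5–1.7.

Two interpretation caveats are built into the code as checks rather
than assumptions. First, "diffusivity along x" is the tensor diagonal
in the *image* frame, so the volume must be axis-aligned with anatomy;
`fit_tensor()` warns if the affine's rotation deviates from
axis-aligned by more than 5°. Second, the ROI mean is computed on one
slice; slab-thickness averaging is not applied (the ROI definition here
is a documented coordinate convention, not an interactive drawing).

## What the phantom emulates — and what it does not

`alps_plane_phantom()` builds a 20×14×3 grid with four 5×5 fiber
patches (projection and association, each hemisphere) in an isotropic
background of 0.8×10⁻³ mm²/s. The default ground-truth diagonals,
projection (1.107, 0.600, 1.400)×10⁻³ and association
(0.885, 1.400, 0.600)×10⁻³ mm²/s, give a left index of exactly 1.66,
a published healthy-control value; the alternative pair
(1.008, …)/(0.840, …) gives 1.54, a published patient value. The
acquisition default is one b = 0 volume plus 32 directions at
b = 1000 s/mm², matching a clinical single-shell protocol. Directions
are a spherical-Fibonacci spread under a seeded random rotation — any
well-conditioned scheme is equivalent for tensor fitting; the
degenerate n = 6 Fibonacci configuration is replaced by the classical
icosahedral six-direction scheme.

Noise, when enabled, is Rician:
$S' = \sqrt{(S+\varepsilon_1)^2 + \varepsilon_2^2}$ with
$\varepsilon_i \sim N(0, S_0/\mathrm{SNR})$, the standard model for
magnitude MRI. The phantom does not simulate susceptibility artifacts,
eddy currents, motion, partial-volume mixing at patch borders beyond
voxel quantization, or anatomical variability in ROI placement. A
passing phantom suite therefore shows that the *computational* chain is
correct and exact, not that the index is robust to real-world
acquisition physics.

## The synthetic cohort generator

`cohort_sim_params()` defaults encode the study conditions the package
analyzes: 61 patients and 38 controls; patients split into two latent
subgroups of 37 and 24 with left/right ALPS Gaussians
(1.66 ± 0.13, 1.44 ± 0.18) and (1.39 ± 0.20, 1.60 ± 0.23); controls at
(1.66 ± 0.15, 1.63 ± 0.15); patient age 43.7 ± 13.5 years (controls
42.9 ± 7.9) with patient ALPS shifted by a −0.005 index/year slope
about the mean age, producing the negative age association. The slope
value is a choice within the reported qualitative finding (older
patients have lower indices); the sign is the constraint, the magnitude
is set so the age effect is visible at n = 61 without dominating the
subgroup structure. The source tables report patient mean age
inconsistently in two places (43.7 ± 13.5 in the cohort table, 58.3 ±
10.3 in the text); the generator defaults to the cohort-table value and
exposes the parameter, asserting neither as correct.

Clinical scores are truncated Gaussians on each scale's admissible
range (MoCA 0–30, FSS 9–63, PSQI 0–21, PHQ-9 0–27, GAD-7 0–21, HAMD
0–52, HAMA 0–56). Each scale carries an abnormality cut-off (MoCA
strictly below 26; the others inclusively at or above 36, 8, 10, 10,
17, 14 respectively — the source text uses strict and inclusive wording
inconsistently, so strictness is configurable) and a target expected
abnormality fraction (e.g. 11/61 for MoCA). Calibration fixes the
Gaussian σ at the printed SD and solves the latent location μ by
monotone root-finding so the truncated distribution's expected
exceedance equals the target. Matching the printed mean *and* SD *and*
tail fraction simultaneously is infeasible for this two-parameter
family on the strongly skewed scales (for GAD-7, mean 2.8 and SD 4.1
bound the achievable tail mass beyond 10 well under the 6.6% target),
so the exceedance expectation — the quantity the downstream flagging
analysis consumes — is the calibrated one, and the realized mean drifts
upward on skewed scales. Scores are kept continuous; integer rounding
would perturb the calibrated tail without adding fidelity the analyses
use.

## Subgrouping

Patient subgrouping clusters the feature pair (left ALPS, left − right
difference), which separates subjects by *which* hemisphere declined.
Clustering is agglomerative with Ward linkage on Euclidean distance —
variance-minimizing, hence matched to the sums-of-squares objective of
the Calinski-Harabasz criterion used for model selection:

$$\mathrm{CH}(k) = \frac{B/(k-1)}{W/(n-k)}$$

with $B$ the between-centroid and $W$ the within-cluster dispersion.
The tree is cut at each k in 2..6 and the argmax selected, ties going
to the smallest k; $W = 0$ returns `Inf` (degenerate duplicated
points). Features are clustered unstandardized by default — both are in
index units on similar scales — with z-scoring available. Average and
complete linkage are provided for sensitivity.

Two honesty notes. First, when the CH curve is nearly flat (maximum
under 1.5× the minimum), `select_k()` warns that the data may hold no
real cluster structure; the full curve is always returned for
inspection. Second, when cohorts are *resimulated* from per-subgroup
summary statistics as independent Gaussians, the two subgroups overlap
more than an empirically derived partition would (a partition produced
by cutting a tree is separated by construction), so the CH-selected k
fluctuates across simulated cohorts; k = 2 is the modal selection
across seeds rather than a near-certain one. The per-seed curve, not
only the argmax, is therefore part of the reported output.

## Statistical engines

Group comparisons follow a clinical-statistics convention: Shapiro–Wilk
on each sample at α = 0.05 gates between a pooled-variance Student t
test and a two-sided Mann–Whitney test (exact via the null U
distribution when both samples have ≤ 20 untied observations, normal
approximation with tie correction otherwise, no continuity correction).
The pooled (rather than Welch) t is the default for summary-statistic
recomputation of published tables, with Welch available. Cohen's d uses
the pooled SD. The 2×2 chi-square is Pearson's without continuity
correction, which is what reproduces the published sex-contrast p-value
from its printed counts. Correlation tests are one-tailed Pearson with
the direction stated explicitly per test — no automatic direction
inference. Regression effects are reported as standardized β: outcome
and covariates z-scored, OLS, two-sided t p-values, with a
condition-number guard (>10⁸ errors) against collinearity. No
multiple-testing correction is applied by default, matching the
analysis convention the package reproduces; `stats::p.adjust` composes
naturally with the tidy outputs if wanted.

Reliability uses ICC(3,1) — two-way mixed-effects, single-measure,
consistency form — computed from the ANOVA mean squares:
$(MS_S - MS_E)/(MS_S + (k-1) MS_E)$. The form is a choice (the
agreement form ICC(2,1) is available); consistency is standard for
intra-rater repeatability, and is offset-invariant. The published ICC
of 0.88 came from a radiologist re-placing ROIs on real scans;
`roi_jitter_reliability()` is an in-silico surrogate (uniform ±j voxel
center perturbations, resampled if out of bounds), useful for
sensitivity analysis but not a reproduction of human placement
variability.

## Numerical choices and degenerate inputs

* Tensor fits clamp negative diagonal estimates to zero and count them
  (`$clamped`); voxels with non-positive signals are excluded and
  counted, not imputed. Constrained positive-definite fitting is out of
  scope — at the SNRs the phantoms use, clamping is essentially never
  triggered.
* `summary_t_test()` with zero variance in both groups errors on equal
  means and returns a signed infinite statistic otherwise.
* `icc_single_rater()` warns on zero between-subject variance and
  returns 1 for identical constant columns (0/0 resolved by the
  identical-ratings limit).
* Merge-order ties in `hclust` and the CH argmax both resolve
  deterministically (lowest index / smallest k), so identical inputs
  give byte-identical outputs; every stochastic stage takes an explicit
  seed and restores the caller's RNG state.
* Problem sizes are chosen for exactness rather than realism: the
  default phantom grid (840 voxels, 33 volumes) is the smallest that
  holds four region-pure 3×3 ROIs with jitter room, and simulation-based
  checks (cluster-number selection, regression recovery) use 200
  replicate cohorts, enough to pin the modal k and mean β estimates
  without heavy runtimes.

## Known limitations

* No DICOM ingestion, no registration, no eddy/motion correction, no
  automated anatomical localization of the ALPS slice on real brains:
  ROI coordinates are the user's responsibility on real data.
* The diagonal-reading of directional diffusivity assumes axis-aligned
  anatomy; oblique acquisitions need resampling before use.
* The cohort generator matches first-order structure (means, SDs, tail
  fractions, one age slope) and leaves out within-subject left–right
  ALPS correlation, score–score correlations, and integer score
  granularity; analyses sensitive to those features should not rely on
  it.
* Patient-vs-control contrasts of the source study (p = 0.005/0.003,
  d = 0.62/0.66) are not recomputable from printed summaries because
  the patient-group SDs are unpublished; the package recomputes what is
  recomputable (subgroup contrasts, proportions, phantom indices) and
  simulates the rest under stated assumptions.
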