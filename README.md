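# alpsindex

Quantifying glymphatic function from diffusion MRI with the DTI-ALPS
index, and running the cohort analyses built on it.

The glymphatic system clears metabolic waste from brain parenchyma
through perivascular fluid exchange. The DTI-ALPS method (diffusion
tensor image analysis along the perivascular space) estimates this
function noninvasively from a single diffusion scan: at the level of the
lateral-ventricle body, medullary-vein perivascular spaces run along the
image x-axis, perpendicular to both the projection fibers (z-dominant)
and the association fibers (y-dominant). Water diffusivity along x in
ROIs placed on those two tracts is elevated when perivascular flow is
intact, so the ratio

```
ALPS = mean(Dxproj, Dxassoc) / mean(Dyproj, Dzassoc)
```

of ROI-mean tensor diagonal diffusivities is a dimensionless index of
glymphatic function; lower values indicate impairment.

`alpsindex` implements the full pipeline in tidyverse-style R:

* **Synthetic data** — DWI phantoms with known ground-truth tensors at
  the ALPS plane (monoexponential signal, optional Rician noise) and
  simulated patient/control cohorts with a bivariate ALPS subgroup
  mixture, an age–ALPS association and clinical scores calibrated to
  target abnormality fractions (`alps_plane_phantom()`,
  `simulate_dwi()`, `simulate_cohort()`).
* **Tensor fitting** — log-linear OLS/WLS diffusion-tensor estimation
  with diagonal-diffusivity, FA and direction-color maps
  (`fit_tensor()`, `diagonal_maps()`, `fa_map()`).
* **ALPS core** — ROI placement, directional diffusivities, left/right
  indices, and placement-reliability ICC (`compute_alps()`,
  `icc_single_rater()`, `roi_jitter_reliability()`).
* **Cohort statistics** — threshold flagging with the seven clinical
  scales (MoCA, FSS, PSQI, PHQ-9, GAD-7, HAMD, HAMA), normality-gated
  two-sample tests, summary-statistic t tests and Cohen's d, one-tailed
  Pearson correlation, 2x2 chi-square, standardized multiple regression
  (`flag_thresholds()`, `two_sample_compare()`, `summary_t_test()`,
  `standardized_regression()`).
* **Subgrouping** — Ward hierarchical clustering on (left ALPS,
  left − right difference) with Calinski-Harabasz pseudo-F selection of
  the number of subgroups over k = 2..6 (`build_features()`,
  `select_k()`, `subgroup_report()`).
* **Reporting** — demographics and subgroup tables, a one-call pipeline
  writing a reproducible artifact bundle (`make_table1()`,
  `make_table2_3()`, `run_pipeline()`).

I/O uses standard formats throughout: NIfTI-1 volumes with FSL-style
`.bval`/`.bvec` sidecars, CSV cohort tables, Newick dendrograms.

## Worked example

A noise-free phantom with healthy-control ground-truth tensors, fitted
and read out end to end:

```r
library(alpsindex)

gtab    <- make_gradient_table(32, b = 1000, n_b0 = 1, seed = 1)
phantom <- alps_plane_phantom()      # projection (1.107, 0.600, 1.400)e-3,
                                     # association (0.885, 1.400, 0.600)e-3
sim  <- simulate_dwi(phantom, gtab)
tf   <- fit_tensor(sim$dwi)
alps <- compute_alps(tf, phantom_roi_set(phantom))
alps
#> <alps_result> left 1.660, right 1.660, diff +0.000
```

The left index equals the closed-form ratio
mean(1.107, 0.885)/mean(0.600, 0.600) = 1.66 because the log-linear fit
is exact on noise-free monoexponential data.

A simulated 61-patient / 38-control cohort, subgrouped by Ward
clustering with Calinski-Harabasz selection:

```r
cohort <- simulate_cohort(cohort_sim_params(seed = 4))
sol    <- select_k(build_features(cohort))
sol$ch
#> # A tibble: 5 × 2
#>       k    ch
#>   <int> <dbl>
#> 1     2  98.3
#> 2     3  87.4
#> 3     4  85.1
#> 4     5  81.4
#> 5     6  82.9
glance(sol)
#> # A tibble: 1 × 6
#>       n linkage  kmin  kmax selected_k ch_max
#>   <int> <chr>   <int> <int>      <int>  <dbl>
#> 1    61 ward        2     6          2   98.3
```

The pseudo-F peaks at k = 2: the cohort splits into a subgroup with a
lower right index and one with a lower left index. Subgroup contrasts
come back tidy (here left ALPS differs at p = 1.9e-11 between the two
subgroups of this simulated cohort). The selected k varies from one
simulated cohort to the next — two is the modal choice across seeds,
and the CH curve is returned so flat selections can be inspected.

Summary-statistic engines reproduce published-table arithmetic exactly:

```r
summary_t_test(1.66, 0.13, 37, 1.39, 0.20, 24)
#> # A tibble: 1 × 7
#>   test      statistic    df      p_value tails effect effect_name
#> 1 student-t      6.40    59 0.0000000277 two       NA <NA>
cohens_d(1.66, 0.13, 37, 1.39, 0.20, 24)
#> [1] 1.677534
```

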