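# infantflow

Cerebral blood flow (CBF) rises faster during infancy than in any later
period of life, and different cortical territories mature on different
schedules. `infantflow` is an R package plus an analysis workflow for
studying that process: it quantifies CBF from perfusion MRI signals,
models its developmental trajectory, finds the ages at which growth
changes pace, parcellates the cortex by its perfusion dynamics, and
relates regional CBF to infant behavior. A synthetic cohort generator
with known ground truth makes every stage testable end to end.

## What it computes

**Quantification.** Global CBF from phase-contrast MRI as the summed
blood flux through the four feeding arteries over the brain mass,

    globalCBF = 100 * sum(flux) / (rho * brainVolume),   rho = 1.06 g/mL

and regional CBF (rCBF) from pseudo-continuous arterial spin labeling
(pCASL) with the single-compartment kinetic model

    rCBF = 6000 * lambda * dM * exp(PLD / T1a) /
           (2 * alpha * M0 * T1a * (1 - exp(-LabelDur / T1a)))

with lambda = 0.9 ml/g, alpha = 0.86, T1a = 1.8 s, PLD = 1.8 s,
LabelDur = 1.6 s, calibrated so the mask-mean rCBF equals the
phase-contrast global CBF. Test-retest agreement is summarized by
ICC(2,1).

**Motion QC.** Per-volume relative RMS displacement from 6-parameter
rigid realignment tables (Jenkinson sphere formulation, 50 mm radius),
the mean relative displacement (MRD) summary, scrubbing of volumes with
displacement > 0.5 mm, and exclusion of subjects with MRD > 0.5 mm.

**Trajectories.** Five candidate growth models (linear, logarithmic,
exponential, Poisson, quadratic) compared by AIC and Akaike weights;
voxel-wise `rCBF ~ log(age) + sex + motion` fits with signed probit Z
maps and Bonferroni thresholds; fitted rCBF maps at 55 ages from 1 to
28 months; growth-rate maps `beta / age`.

**Breakpoints.** Continuous piecewise-linear (segmented) regression with
0-3 breakpoints fitted by iterative linearization, profile-likelihood
confidence intervals, ANOVA comparison of nested breakpoint counts, and
voxel-wise breakpoint maps.

**Parcellation.** Orthonormal projective non-negative matrix
factorization (opNMF), `min ||X - W W'X||_F^2` with `W >= 0` and
`W'W ~ I`, hard labels by maximal weight, and component-count selection
over K = 2..20 with the Davies-Bouldin and Calinski-Harabasz indices.

**Spatial statistics.** Pearson correlation of voxel-wise maps, a
free-shuffle permutation null (10,000 surrogates), and alignment
trajectories of the fitted map stack against a reference pattern such as
an adult cerebral-metabolism map.

**Behavior.** Generalized additive models
`rCBF ~ score + s(age) + sex + motion + SES` with penalized cubic
regression splines, voxel t-maps thresholded at t > 2.02 with a
100-voxel cluster extent, and cluster-level tests at the 0.05/3 domain
threshold.

## Worked example

```r
library(infantflow)

# a global-CBF cohort following CBF = 16.38 ln(age) + 16.85
d <- generate_global_cohort(119, "logarithmic", seed = 5)
fits <- fit_candidate_models(d$age, d$global_cbf)
fits[order(fits$aic), c("family", "d_aic", "w_aic")]
#>       family     d_aic        w_aic
#>  logarithmic  0.000000 9.912247e-01
#>    quadratic  9.458651 8.754918e-03
#>       linear 21.617662 2.004271e-05
#>  exponential 29.951535 3.106554e-07
#>      poisson 40.579513 1.529124e-09

# a biphasic cohort: where does growth change pace?
b <- generate_global_cohort(119, "biphasic", seed = 5)
fit_segmented(b$age, b$global_cbf, n_breakpoints = 1)
#> Segmented fit: 1 breakpoint(s), n = 119 [iterative]
#>   psi1 = 10.775 (SE 0.738, 95% CI 9.23-11.97)
#>   slopes: 3.726, 0.524
#>   RSS 5064.591, adj R2 0.6759
```

The logarithmic family takes essentially all the Akaike weight on
logarithmic data, and the breakpoint lands near the generating value of
10.75 months with first/second-phase slopes near 3.52 and 0.43
ml/100g/min per month.

The full analysis — cohort simulation, quantification, motion QC,
trajectory modeling, segmented regression, opNMF parcellation, spatial
alignment and behavior association — runs as numbered scripts:

```sh
Rscript analysis/01_simulate_cohorts.R
Rscript analysis/02_quantify_cbf.R
# ... through analysis/08_behavior.R
```

Each script prints what it found and writes its tables under `results/`.

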