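---
title: "Models and methods behind infantflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind infantflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infantflow)
```

`infantflow` analyzes the development of cerebral blood flow (CBF)
across infancy: how fast perfusion rises, when its growth changes pace,
how those dynamics organize the cortex into territories, and how
regional perfusion relates to emerging behavior. This vignette explains
the models the package implements, the choices made where the design was
genuinely open, and what the synthetic test cohorts do and do not show
about real data.

## Quantification

Global CBF comes from phase-contrast MRI: the blood flux (ml/min)
through the four feeding arteries (both internal carotids, both
vertebrals), divided by the brain parenchyma mass,

$$\mathrm{CBF}_{g} = \frac{100 \sum_a \mathrm{flux}_a}{\rho \cdot V},$$

with tissue density $\rho = 1.06$ g/mL and $V$ the gray + white matter
volume in mL; the factor 100 converts to ml/100g/min.

Regional CBF comes from pCASL with the single-compartment kinetic model

$$\mathrm{rCBF} = \frac{6000\,\lambda\,\Delta M\,e^{PLD/T_{1a}}}
{2\,\alpha\,M_{0}\,T_{1a}\left(1 - e^{-\tau/T_{1a}}\right)},$$

where $\Delta M$ is the mean control-minus-label difference, $M_0$ the
equilibrium magnetization (the average of an acquired pair), $\lambda =
0.9$ ml/g the blood-brain partition coefficient, $\alpha = 0.86$ the
labeling efficiency, $T_{1a} = 1.8$ s the arterial blood T1, $PLD =
1.8$ s the post-labeling delay and $\tau = 1.6$ s the labeling
duration. All times are stored in seconds so the 6000 factor yields
ml/100g/min directly; millisecond inputs are converted at the
configuration boundary. Because $\alpha$ and $T_{1a}$ vary across
infants, each rCBF map is rescaled by the single factor that makes its
mask mean equal the phase-contrast global CBF. Calibration is a positive
scalar, so it preserves the spatial pattern exactly and is idempotent.

Scrubbing removes whole control/label *pairs*: an unpaired subtraction
is undefined, so if either member of a pair moved too much the pair is
dropped. Test-retest reliability uses ICC(2,1) — two-way random
effects, absolute agreement, single measurement — treating masked
voxels as targets and scans as raters, with the F-based 95% interval.

## Motion

Head motion is summarized from 6-parameter rigid realignment tables
(rotations in radians, then translations in mm — the MCFLIRT order).
The displacement between consecutive volumes is the RMS displacement of
a 50 mm sphere under the relative transform,
$\sqrt{R^2\,\mathrm{Tr}(A^\top A)/5 + t^\top t}$ with
$A = M_{rel}[1:3,1:3] - I$. For pure translations this is the
translation magnitude regardless of radius, which makes the metric easy
to validate. The sphere radius is configurable; 50 mm is a reasonable
upper bound for an infant head and only affects the rotational term.
The subject summary (MRD) is the mean of the per-volume series computed
*before* scrubbing, so that the QC covariate reflects the scan as
acquired. Volumes above 0.5 mm relative displacement are scrubbed;
subjects above 0.5 mm MRD are excluded; both thresholds are strict
inequalities.

## Developmental trajectories

Five families are candidates for CBF growth: linear, logarithmic
(`y ~ ln(age)`), exponential ($y = a e^{b\,\mathrm{age}}$, nonlinear
least squares with a log-linear start), Poisson (log-link GLM; the
response is rounded so the Poisson likelihood is defined — a documented
approximation isolated behind the family interface), and quadratic.
Models are ranked by $\mathrm{AIC} = -2\ln L + 2k$ with $k$ counting
every estimated parameter including the residual variance, and compared
through Akaike weights $w_i \propto e^{-\Delta_i/2}$, interpretable as
the probability of being the best model in the set.

All `log(age)` terms use the natural logarithm: evaluating the global
curve $16.38\ln(\mathrm{age}) + 16.85$ gives physiologically sensible
values at both extremes (about 17 ml/100g/min at 1 month, about 71 at
28 months), which base-10 logs do not.

Voxel-wise fits share one design matrix, so the whole gray-matter
matrix is fitted with a single QR decomposition. The age effect is
reported as a signed probit statistic $Z = \mathrm{sign}(\beta)\,
\Phi^{-1}(1 - p/2)$; the quantile is evaluated on the upper tail
(`lower.tail = FALSE`) because $1 - p/2$ rounds to 1 in double
precision once $p < 10^{-17}$. Bonferroni correction over $m$ voxels
thresholds at $p < \alpha/m$; over 144,237 gray-matter voxels at
$\alpha = 0.05$ this is $3.47\times10^{-7}$, i.e. $|Z| > 5.1$.

Fitted map stacks evaluate each voxel's model at ages 1 to 28 months in
steps of 0.5 (55 maps), fixing head motion at the cohort-average MRD
and averaging the sex effect over both levels (the mean of the
predictions at sex 0 and 1). Growth-rate maps are the analytic
derivative of the logarithmic fit, $\beta/\mathrm{age}$.

## Segmented regression

Breakpoints are estimated by iterative linearization: at the current
estimate $\psi$ the model is regressed on $x$, the hinge $(x-\psi)_+$
and the indicator correction $-\mathbb{1}(x>\psi)$, and the coefficient
ratio of correction to hinge gives the update. Two robustness measures
were needed in practice. First, the raw update can oscillate; each step
is therefore halved until the profile residual sum of squares does not
increase, which makes the iteration monotone and guarantees
termination. Second, the one-breakpoint profile has local minima, so
the iteration starts from the best inter-observation midpoint of a full
profile screen, which on simulated cohorts reproduces a 0.05-month grid
search to within one grid step.

The first-order delta-method standard error
$SE(\psi) = SE(\gamma)/|\beta_U|$ is reported, but it ignores the
curvature of the profile: on simulated biphasic cohorts its 95%
interval covered the true breakpoint only about 87% of the time
(empirical SD 0.96 months versus mean reported SE 0.71). The default
one-breakpoint interval therefore inverts the extra-sum-of-squares F
test over the profile instead, which covers about 93% in the same
simulations; the delta interval remains available via `ci = "delta"`.
Each phase must contain at least three observations, otherwise the
phase slope standard error is undefined and the fit errors. Nested
breakpoint counts (0-3) are compared by the extra-sum-of-squares F
test, counting two parameters (hinge coefficient and breakpoint
location) per breakpoint; the count grows while the test is significant
and the adjusted R² improves. When covariates are supplied they are
residualized out of the response first, since a piecewise model with
simultaneous linear covariates is not what the breakpoint machinery
estimates.

## opNMF parcellation

The voxel-by-subject rCBF matrix $X$ is factorized as $X \approx W H$
with $H = W^\top X$, $W \ge 0$, and $W^\top W$ driven toward the
identity by the projective multiplicative update
$W \leftarrow W \circ (XX^\top W) \oslash (W W^\top X X^\top W)$ with
column renormalization. Orthonormality is a soft property of this
scheme: the residual off-diagonal mass of $W^\top W$ is reported, not
enforced. The objective $\|X - WW^\top X\|_F^2$ is guarded to be
non-increasing by blending each raw multiplicative step back toward the
previous iterate whenever it would increase the objective.

Initialization matters more than iteration count here. From a generic
NNDSVD or random start the multiplicative updates stall in local optima
roughly an order of magnitude above the noise floor on cohort-like
data, while a start informed by any reasonable partition reaches the
floor in a handful of iterations. The default policy therefore runs the
update from an NNDSVD start, a kmeans-indicator start (floored at a
small positive value so mass can still move between components), and
seeded random restarts, and keeps the lowest-objective solution. The
K-selection sweep uses the kmeans-seeded start alone, since it wins in
practice and the sweep fits nineteen values of K.

Hard labels are the row-wise argmax of $W$ (ties to the lowest index;
all-zero rows are counted as unassigned). Component count is chosen
over K = 2..20 by computing the Davies-Bouldin (lower better) and
Calinski-Harabasz (higher better) indices on the voxels'
subject-profile rows under the hard labels — the natural feature space,
since those rows are the objects being clustered — and taking the K
with the best summed rank, ties to the smaller K.

## Spatial statistics

Map alignment is the Pearson correlation over masked voxels.
Significance comes from a free-shuffle permutation null: masked values
of one map are re-assigned uniformly (10,000 surrogates by default) and
the one-sided empirical p is $(\#\{r_{null} \ge r_{obs}\} + 1)/(n+1)$,
so the smallest reportable value is $1/10001 \approx 10^{-4}$. Free
shuffling ignores spatial autocorrelation; with the default generator's
independent voxel noise that is exact, but on smooth real maps it
overstates significance — a known limitation, as autocorrelation-
preserving nulls are out of scope. The alignment trajectory correlates
each of the 55 fitted maps with a reference pattern; on the synthetic
cohort it rises monotonically and turns positive near the global
breakpoint age, reflecting the generator's diverging cluster
trajectories.

## Behavior association

Associations between rCBF and Bayley-like standard scores use
`rCBF ~ score + s(age) + sex + motion + SES` with a penalized cubic
regression spline for age (basis dimension 5, smoothing by GCV): with
49 complete subjects a richer basis is not supportable, and the spline
must absorb both linear and logarithmic-shaped age trends so the score
term is tested conditional on development. With the penalty forced
high, the score t-statistic converges to the linear-age model's, and
with a log-shaped age effect it matches an oracle that enters the true
log term parametrically. GCV smoothing makes the voxel-level null
rejection rate sit slightly above the nominal 5%, a known property of
GCV rather than an implementation artifact.

Voxel t-maps are thresholded at t > 2.02 (positive tail, matching the
directional hypothesis of faster-growing regions supporting emerging
skills) and clustered by 26-connectivity with a 100-voxel (800 mm³ at
2 mm isotropic) minimum extent; 6 and 18-neighborhoods are available.
Cluster-level tests on parcel-mean rCBF use the Bonferroni threshold
0.05/3 = 0.0167 across the three behavioral domains.

## The synthetic cohort

The generator produces the data structures every stage consumes, with
known ground truth:

- **Ages** are truncated-normal (mean 12.5, SD 7.1 months) on
  [1.4, 28], matching the study cohort's demographics; uniform sampling
  is available.
- **Global CBF** follows $16.38\ln(\mathrm{age}) + 16.85$ or a
  two-phase line with slopes 3.52 and 0.43 ml/100g/min per month
  breaking at 10.75 months, anchored to meet the logarithmic curve at
  the breakpoint. The residual SD defaults to 6.3 ml/100g/min,
  calibrated by simulation so the age-CBF correlation at n = 119 is
  about 0.82; the signal SD of the logarithmic curve under this age
  distribution is about 9.3, so larger residuals would understate the
  age effect relative to what perfusion cohorts of this size report.
- **Regional maps** live on a 20 x 24 x 20 grid (2 mm voxels) inside an
  ellipsoidal mask of about 2,200 voxels, partitioned radially into a
  limbic core (25%), sensorimotor shell (35%) and frontoparietal rim
  (40%). Each cluster follows a two-phase trajectory with breakpoints
  at 6.71, 7.69 and 10.36 months. The phase slopes are not reported
  quantities, so they were chosen once, by a design-time search, to
  satisfy three structural requirements simultaneously: the three mean
  trajectories are mutually near-equidistant in subject-profile space
  (otherwise Euclidean validity indices prefer merging the closest
  pair, and no three-cluster solution can win at any noise level);
  every cluster has a slope change large enough for its breakpoint to
  be identifiable at the cohort's noise; and the logarithmic age slopes
  order frontoparietal > sensorimotor > limbic, the hierarchy the
  voxel-wise models should recover. The defaults give a limbic cluster
  that rises early then plateaus (intercept 23.4, slopes 3.64 then
  0.06), a sensorimotor cluster with the steepest first phase (15.2,
  6.91 then 0.02), and a frontoparietal cluster that starts lowest and
  keeps rising fastest after its late breakpoint (10.4, 3.65 then
  2.84); see `default_cluster_params()`.
- **Noise** has two parts: a per-(subject, cluster) residual (SD 6.3)
  and i.i.d. voxel noise (SD 10). The residual is cluster-specific
  rather than brain-wide so that a behavior score loaded on one
  cluster's age-adjusted mean does not correlate with every other
  cluster through a shared global offset. There is no spatial
  autocorrelation by default, so cluster-extent thresholds behave
  conservatively on generated maps. Values are floored at 0.1
  ml/100g/min to keep rCBF physically positive; the floor affects well
  under 1% of voxels and biases young-age means negligibly.
- **ASL and PC signals** are generated by inverting the quantification
  equations, so with zero measurement noise the quantify-generate round
  trip is exact to numerical precision — the property the
  quantification tests rely on.
- **Motion** tables are pure-translation random walks whose step sizes
  are scaled so each subject's realized MRD equals a target drawn from
  a gamma distribution with mean 0.22 and SD 0.13 mm, truncated below
  the exclusion threshold.
- **Behavior scores** are mean-100, SD-15 standard scores constructed
  as `100 + 15 (rho z + sqrt(1 - rho^2) noise)` where z is the
  standardized age-adjusted cluster-mean rCBF residual and rho (default
  0.5) the configured partial correlation. Motor loads on the
  sensorimotor cluster, language on frontoparietal, cognitive on
  limbic.

What passing tests on this cohort show — and what they do not. The
generator exercises the statistical machinery under exactly the
assumptions the methods make: independent Gaussian noise, correctly
specified trajectory families, clusters that differ in mean profile.
Real infant perfusion data violate all three in degree: spatial
autocorrelation, partial-volume and transit-time effects, registration
error, and trajectory shapes that are only approximately logarithmic.
Recovery of generator parameters therefore validates the estimators,
not the biology; conclusions about real cohorts still require the
original data.

## Problem sizes and determinism

Simulation-based checks use 50 replicate cohorts for model selection
and breakpoint recovery, 20 for component-count selection, and 200 for
interval coverage — sizes at which medians of recovered parameters are
stable to well within the tolerances being checked. Every random draw
flows from a single integer seed per cohort, so all results are exactly
reproducible; opNMF's multi-start and kmeans initializations are seeded
the same way.

## Known limitations

Breakpoints inside nonlinear base curves (e.g. a segmented logarithm)
are not modeled; the piecewise-linear form is the estimand. The
exponential family can fail to converge on pathological data, in which
case model selection proceeds without it only if explicitly requested —
by default the error propagates. Permutation nulls do not preserve
spatial autocorrelation. The Poisson family's rounding approximation
makes its likelihood non-comparable in the tails; it never wins on
realistic CBF data, which is the point of including it as a contrast.
The frontoparietal breakpoint is the hardest recovery target: its
slope change is modest, so single-cohort estimates scatter widely and
only the median over tens of cohorts is stable.
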