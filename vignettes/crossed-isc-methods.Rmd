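---
title: "Methods: inter-subject correlation with crossed random effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inter-subject correlation with crossed random effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossisc)
```

## The problem

When several subjects passively view the same time-locked naturalistic
stimulus (a movie), the stimulus drives a shared component of the BOLD
response at cortical locations that process it. The Pearson correlation
between two subjects' time series at the same surface node — the
inter-subject correlation (ISC) — indexes that shared processing. Group
questions then become questions about the $N \times N$ matrix of pairwise
ISCs at each node: how strongly does a group synchronize internally, does
one group synchronize more than another, and does a child's synchrony with
an adult reference group (neural maturity) grow with age?

The statistical obstacle is that the $\binom{N}{2}$ pairwise values are not
independent: every subject contributes to $N-1$ of them. `crossisc`
implements the crossed random-effects treatment of this dependence, along
with the preprocessing, ISC computation, and cluster-level inference that
surround it.

## Pipeline and model

### Motion and censoring

Head motion is summarized per volume as framewise displacement,
$FD_i = |\Delta d_{ix}| + |\Delta d_{iy}| + |\Delta d_{iz}| +
|\Delta\alpha_i| + |\Delta\beta_i| + |\Delta\gamma_i|$, the sum of absolute
backward differences of the six rigid-body parameters. Rotations are
converted to arc length on a 50 mm sphere by default
(`rotation_radius_mm = 50`), the convention of the scrubbing literature;
`rotation_radius_mm = 0` reproduces the literal unconverted sum for
pipelines that report raw angular values — the formula itself does not fix
the units, so both are exposed. The first volume's FD is defined as 0 so
masks align with the run.

Volumes with FD strictly above 0.5 mm are censored, and a run is excluded
when the censored count reaches the smallest integer strictly greater than
9% of the volume count — 16 volumes for a 176-volume run. Both comparisons
are strict ("exceeded", "> 9%"). Whether the 9% bound should be taken on
176 retained or 180 acquired volumes is immaterial: both give 16.

### One nuisance regression

All signals of no interest are removed in a single per-node ordinary
least-squares regression: an intercept, orthogonal polynomial trends of
order 1–3, demeaned motion parameters and their backward-difference
derivatives (first element 0, matching FD's convention), white-matter and
ventricle means, and optionally the mean signal of a frontal-eye-field
(FEF) region as an attention-control regressor.

Temporal filtering to a 0.01–0.1 Hz retention band is implemented as
*regressors* — sine/cosine pairs at every DFT frequency of the run that
falls outside the band (the sine at Nyquist, identically zero, is omitted)
— rather than as a filter. This is the standard way to preserve temporal
continuity under censoring: censored volumes are simply omitted from the
regression (row deletion, not zero-weighting or interpolation), and their
positions are kept as flagged `NA` gaps in the residuals. Downstream ISC
then drops gaps pairwise. Row omission was chosen over interpolation
because it leaves censored volumes with provably zero influence on the
fit; the suite tests exactly that.

The design's condition number (after column scaling, on kept rows) is
reported on every build, and estimability is checked by rank on the kept
rows with the offending columns named.

One practical consequence worth knowing: regressing out twelve
motion-derived columns, whose spectra are drift-dominated, removes
low-frequency variance where a smooth stimulus-driven signal also lives.
On synthetic data this attenuates pairwise ISC below the generator's
closed-form expectation even though every step is correct. For this reason
the oracle-recovery tests compare ISC of *unfiltered* generator output to
the closed form, while the preprocessing stage is tested by its own
contracts (orthogonality, zero influence of censored rows, projection
idempotence).

### Surface smoothing and clusters

The mesh is a triangulated surface with per-node areas assigned by the
barycentric one-third rule (each triangle's area split equally among its
corners), so node areas partition the total surface area exactly.
Smoothing is iterative nearest-neighbour averaging, with each step's
weights summing to one per node (constants are preserved exactly, and the
operator is linear). The step count is calibrated by measuring the spatial
variance of a smoothed point source on the actual mesh and stopping at the
count whose spread best matches the requested Gaussian FWHM
($\mathrm{FWHM} = \sqrt{8\ln 2}\,\sigma$; a surface point response is
two-dimensional, so the target total variance is $2\sigma^2$). Calibration
by measurement rather than a heat-kernel closed form was chosen because
toy meshes are irregular. On a regular 1 mm grid the delta response
achieves the requested 7 mm FWHM within the suite's 15% check; the
discreteness of the step count is the main residual error.

Clusters are maximal connected components of supra-threshold nodes
($p <$ threshold, strict) under shared-edge adjacency — the standard
surface-cluster convention — with component area the sum of member node
areas. Components below the extent threshold are discarded.

### The crossed random-effects model

Each pairwise Fisher-z ISC carries random intercepts for both contributing
subjects:

$$z_{ij} = \mathbf{x}_{ij}'\boldsymbol\beta + a_i + a_j + e_{ij},
\qquad a \sim N(0, \tau^2),\; e \sim N(0, \sigma^2).$$

Marginally $\mathbf V = \sigma^2 I + \tau^2 Z Z'$ with $Z$ the
pair-to-subject incidence (two 1s per row). For child $\times$ adult
blocks the two memberships come from different pools and carry separate
components $\tau^2_{child}, \tau^2_{adult}$ (crossed factors). Estimation
is REML: $\sigma^2$ is profiled out and the variance ratio(s)
$\gamma_k = \tau^2_k/\sigma^2$ optimized (one-dimensional golden-section /
low-dimensional L-BFGS-B on the log scale, bounded at the 0 boundary);
every $\mathbf V^{-1}$ product uses the Woodbury identity on the
incidence, so a fit costs $O(n_{pairs} N^2)$ rather than
$O(n_{pairs}^3)$. The suite verifies the fit against an independent
dense-covariance oracle (explicit $\mathbf V$, generic optimizer) to
$10^{-6}$ in coefficients and REML log-likelihood.

**Both triangles.** Group analyses of a symmetric correlation matrix are
often written over both triangles so that each subject appears
symmetrically. Duplicated rows carry no information, and fitting them as
if independent would halve standard errors. `fit_crossed_lmm(doubled =
TRUE)` therefore deduplicates to the single triangle (verifying symmetry)
and models the exact pair covariance; doubled and single-triangle inputs
give identical estimates, standard errors, and df by construction. This is
this package's resolution of how duplicated rows' residual correlation
should be treated, and it is asserted in the tests rather than assumed.

**Inference.** Per-effect $t$ statistics use Satterthwaite denominator
degrees of freedom computed from the REML variance components: $df = 2
f^2 / (\mathbf g' \mathbf A \mathbf g)$ with $f$ the contrast variance,
$\mathbf g$ its numerical gradient in the components, and $\mathbf A$ the
inverse observed REML information (numerical Hessian). The df is clamped
to $[1, n_{pairs} - p]$; when a subject variance is pinned at the 0
boundary the approximation degenerates and the implementation falls back
to the conservative $\min(N) - p$. In balanced intercept-only fits with a
strong subject component the df tracks the subject count (about $N - 1$),
not the pair count — the crossed structure is what prevents the pair count
from masquerading as sample size.

**Model variants.** `within_group_model()` is intercept-only per node
(intercept also reported as $\tanh(\hat\beta)$ on the r scale);
`group_contrast_model()` fits within-A plus within-B pairs with a group
affiliation effect (A - B), *excluding* mixed pairs by default — the
contrast compares internal synchrony levels, and mixed pairs answer a
different question (an `include_mixed` option adds them as a third level);
`child_to_adult_age_model()` fits the child x adult block with crossed
child/adult intercepts and centered child age (months) as the covariate.

### Monte Carlo cluster-extent correction

Null maps are i.i.d. standard normal node values, smoothed with the same
kernel as the data, restandardized by each map's own standard deviation
(smoothing shrinks the marginal variance), converted to two-sided normal
p-values, and clustered at the primary threshold. The maximum cluster area
per simulation forms the null distribution; the extent threshold is its
conservative next-order-statistic $(1-\alpha)$ quantile — with $n$ maxima
sorted ascending, the $\lfloor(1-\alpha)n\rfloor + 1$-th value — and a
cluster survives when its area is at least the threshold. Two-sided
thresholding was chosen because the map's sidedness is analysis-dependent.

Generating null values directly on mesh nodes is a desk-scale stand-in for
simulating noise *volumes* and projecting them to the surface; it
preserves the logic (smoothness-matched nulls, max-statistic FWE) but not
the projection step, and the smoothness of real residual maps is not
estimated from data here. The suite checks the two properties that matter:
empirical FWE on fresh nulls within binomial tolerance of the target, and
extent thresholds that shrink as the primary nodewise p tightens (the
qualitative ordering behind pairing a 315 mm^2 extent with p < 0.05 and a
150 mm^2 extent with p < 0.01). The primary p and extent are deliberately
kept as free parameters of `null_sim_config()`.

## The synthetic cohort generator

Every stage above is exercised on generated cohorts with known truth. At
node $v$, subject $i$'s series is

$$y_{iv}(t) = c_{iv}\, s_v(t) + b\, u_{iv}(t) +
  \sqrt{1 - c_{iv}^2 - b^2}\;\epsilon_{iv}(t),$$

with $s_v$ a shared signal (white noise convolved with a Gaussian of FWHM
3 TRs, mimicking hemodynamic smoothness, then standardized), $u_{iv}$ an
optional subject-idiosyncratic smooth signal, and $\epsilon_{iv}$ AR(1)
noise (lag-1 autocorrelation 0.3 by default). Components are sample-
orthogonalized and standardized, so the expected pairwise correlation has
the exact closed form $E[r_{ij,v}] = c_{iv} c_{jv}$ (`expected_isc()`),
which serves as the oracle throughout the tests. Coupling enters as
correlation-with-shared-signal precisely so that this oracle stays closed
form; additive signal-to-noise parameterizations were rejected because
they make the expected correlation depend on every variance in the model.

Defaults encode the study conditions the pipeline targets: groups of
23/23/21 (two child groups and one adult group, 67 subjects), 176 volumes
at TR 2 s (a 6-minute run), adult coupling 0.6 vs child 0.4, child ages
uniform over 48–84 months (an `age_two_clusters` option reproduces two
narrow bands centred near 53 and 79 months), motion spike rate 0.05, and
an age slope applied to children inside designated effect nodes. The
idiosyncratic coupling $b$ defaults to 0: between-child heterogeneity
beyond independent noise is real but unquantified, so it is exposed as a
knob rather than given a fabricated default. Motion spikes are injected
into the motion parameters only, unless `spikes_affect_signal = TRUE`
couples them into the data for scrubbing-efficacy experiments.

What the generator does *not* emulate: hemodynamic forward models (no HRF
convolution of event streams), volumetric image formation and projection,
spatially correlated noise across nodes, and distance-dependent motion
artifacts. Passing tests therefore demonstrate the statistical machinery
under the stated generative assumptions, not robustness to everything real
data can do.

## Numerical choices and degenerate inputs

* Correlations with $|r| \ge 1 - 10^{-12}$ are clipped to that bound
  before `atanh` and flagged; an infinite z cannot enter the mixed model.
* Pairs with fewer than 100 mutually uncensored volumes (of 176) are
  flagged missing and propagate as missing, never as zeros.
* Zero-mean nodes cannot be scaled to mean 100; they are zeroed, recorded,
  and warned about.
* A constant response (zero residual variance) short-circuits the REML
  optimizer to the exact OLS solution with a `degenerate` flag.
* Variance ratios are optimized on the log scale in
  $[10^{-10}, 10^{6}]$; estimates below $10^{-7}$ are treated as the 0
  boundary and flagged.
* Ties and interpolation in the extent threshold are avoided by the
  next-order-statistic rule, stated bit-exactly above.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
desk scale, chosen to keep the full run in the low minutes on one CPU
while leaving Monte Carlo margins comfortable: study-sized cohorts
(67 subjects, 176 volumes) with 1–3 nodes for recovery checks, 500
replicates for type-I calibration (12 + 12 subjects), 15–100 seeds for
detection and sign-recovery rates, and 500-simulation null distributions
on a 256-node toy mesh for FWE checks. The mixed-model oracle comparisons
use 7–9 subjects where dense-covariance REML is cheap and exact.

## Known limitations

* Each node is fit independently; there is no spatial model across nodes
  beyond the cluster-level correction, matching standard practice.
* Subject random-intercept variances are homoscedastic within a factor; no
  subject-specific variances or longitudinal structure.
* GIFTI XML geometry is not parsed; FreeSurfer ASCII and delimited
  per-node data are the supported text formats.
* The Monte Carlo null is smoothness-matched by construction, not
  estimated from residual maps; if real residuals are smoother than the
  applied kernel the correction is anticonservative. A
  smoothness-matching knob exists (`fwhm_mm`) but no data-driven estimate
  is provided.
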