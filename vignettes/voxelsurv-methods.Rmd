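---
title: "Methods: voxel-based survival risk models with leakage-free multi-site harmonization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-based survival risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

After a first episode of psychosis, some patients relapse within two years
and some do not.  A tool that estimates each patient's relapse risk from
data already collected at baseline — a structural MRI and the routine
clinical scales — could help clinicians decide how intensively to follow up
and whether prophylactic treatment is warranted.  Statistically this is an
individual risk-prediction problem with a right-censored time-to-event
outcome, high-dimensional imaging predictors, and a strong nuisance factor:
the data come from several hospitals whose scanners imprint site-specific
shifts and scalings on the images.

`voxelsurv` implements the full modelling pipeline for this problem:

1. voxel-based-morphometry feature engineering (smoothing, subsampling,
   channel stacking, optional global volumes and midline flags);
2. multi-site harmonization by empirical-Bayes location/scale batch
   correction (ComBat), **estimated on training subjects only** and applied
   frozen to held-out subjects;
3. train-frozen residualization of age and sex from the imaging features
   and min–max scaling of the clinical variables to the unit interval;
4. an L1-penalized (lasso) regression — Cox partial likelihood for
   survival, or gaussian/binomial for benchmark outcomes — with the penalty
   chosen by internal cross-validation;
5. subject-bootstrap or voxel "half-brain" ensembles whose member risk
   estimates are averaged;
6. event-stratified k-fold cross-validation in which *every* estimated
   transform is re-fitted inside each fold; and
7. site-aware evaluation: a Cox model of the outcome on the estimated risk
   group with the site as a Gaussian random intercept, Kaplan–Meier curves,
   and univariate voxelwise survival maps.

A synthetic multi-site cohort generator with known ground truth makes every
stage testable end to end without access to clinical data.

## The model

For subject $i$ let $x_i$ collect the preprocessed voxel values and scaled
clinical variables.  The survival model is a penalized Cox regression: with
Breslow's convention for ties, the fit minimizes

$$ -\tfrac{2}{n}\,\ell(\beta) + \lambda \lVert \beta \rVert_1, $$

where $\ell$ is the log partial likelihood of $\eta_i = x_i^\top\beta$.
The penalty $\lambda$ is selected by internal cross-validation on the
training set (Verweij–van Houwelingen partial-likelihood deviance for Cox;
MSE and binomial deviance for the other families), by default at the
deviance minimum.  A subject's risk estimate is the plain sum
$\sum_j \beta_j x_{ij}$ (averaged over ensemble members); the subject is
called **high relapse risk (HRR)** exactly when that sum is positive
(hazard ratio above 1), with ties at zero assigned to the low-risk group.

Key assumptions: proportional hazards for the risk grouping to be
meaningful; additive site effects on the (roughly Gaussian) voxel
intensities so that location/scale harmonization can remove them; and
linear age/sex effects on the imaging features.

## Leakage discipline

The central engineering contract is that no statistic derived from held-out
subjects ever enters a training-side computation.  Concretely,
`combat_fit()`, `residualize_fit()`, `scale_clinical_fit()`, the univariate
screening and the penalty selection all receive *only* the training rows of
the current fold; their outputs are frozen parameter objects whose apply
steps (`combat_apply()` etc.) are pure functions.  The test suite enforces
this with hash sentinels: mutating held-out subjects must leave every
training-derived parameter bundle bit-identical.

A subject whose site is absent from the training split cannot be
harmonized; such subjects are excluded from that fold's evaluation (with a
note) rather than silently passed through.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `sigma_mm` | 4 mm | Gaussian smoothing kernel σ; FWHM $=2\sqrt{2\ln 2}\,\sigma \approx 9.4$ mm. We use the standard FWHM convention throughout. |
| `subsample_mm` | 12 mm | block-mean pooling target ("triple subsampling" from 3 mm voxels); modulated channels are rescaled by $k^3$ so block totals (absolute tissue volume) are preserved. |
| `channels` | all four | unmodulated + modulated gray and white matter; the channels carry complementary concentration vs. volume information. |
| `ensemble_method` | `"voxels"` | 18 half-brain members: planes through the mask centroid at evenly spread angles (spherical Fibonacci directions under a seeded rotation). Clinical columns are kept in every member; only the voxel block is split. |
| `n_members` | 18 | ensemble size for both methods. |
| `n_folds` | 10 | outer folds, event-stratified (per-fold event counts differ by at most one). |
| `inner_folds` | 5 | folds of the internal penalty selection. With realistic event counts (tens of events in a training split) 5 folds keep several events per inner fold; 10-fold inner CV is available but doubles the compute for no measurable gain in the selected penalty. |
| `screen_alpha` | off | optional univariate screening (per-voxel Cox score test at uncorrected $P<\alpha$); non-voxel columns are always kept, and an empty surviving set falls back to all voxels. |
| `lambda_rule` | `"min"` | deviance-minimizing penalty; the 1-SE rule is available. |

## Numerical choices

* **Solver.** Cyclic coordinate descent on the IRLS quadratic
  approximation with soft-thresholding, warm starts along a log-spaced
  $\lambda$ grid, sequential strong-rule screening with full KKT
  verification, and active-set iteration.  `lasso_fit()` declares
  convergence when a full pass changes no coefficient by more than `tol`
  (default $10^{-7}$ on the standardized scale) and the KKT conditions hold
  over all columns.  Features are standardized internally (mean 0, SD 1
  with the $1/n$ convention); coefficients are reported on the original
  scale.  The Cox objective is scaled by $2/n$; note glmnet scales by
  $1/n$, so our $\lambda$ equals twice glmnet's for the same Cox solution.
* **Path termination.**  The path stops early when the deviance ratio
  saturates or stops improving, when the linear predictor explodes (a
  separating direction makes the likelihood flat), when a $\lambda$ fails
  to converge within its cycle budget (unconverged solutions are never
  returned), or — Cox only — when the number of nonzero coefficients
  exceeds the event count, which the partial likelihood cannot support.
  Cross-validated selection then uses the grid prefix that every fold
  evaluated.  On realistic cohorts the selected $\lambda$ sits around
  $0.4$–$0.6\,\lambda_{\max}$, far from any truncation point.
* **Ensemble member fits** use a 30-point grid down to
  $0.05\,\lambda_{\max}$ and `tol` $10^{-4}$: member risk scores are
  insensitive to tighter settings (identical to about three decimals), and
  the pipeline fits hundreds of members, so the looser member numerics buy
  an order of magnitude of speed at no measurable cost to the risk
  estimates.
* **ComBat.**  Parametric empirical-Bayes priors (normal on location,
  inverse-gamma on scale), the standard iterative conditional solution with
  relative-change tolerance $10^{-6}$ (cap 500 iterations), and a
  $\delta$ floor of $10^{-8}$ for degenerate sites.  No covariates are
  passed by default — age and sex are handled by the separate
  residualization step, matching the two-stage structure of the procedure —
  but a covariate hook is provided.  Our fit+apply on training data matches
  `sva::ComBat` to $10^{-7}$ at 200 subjects per site (sva stops its EB
  iteration earlier, which dominates the difference on small fixtures).
* **Smoothing** uses a sampled Gaussian kernel truncated at
  $\lceil 4\sigma \rceil$ voxels, normalized to unit sum, applied
  separably per axis with zero padding outside the grid; the mask is
  re-applied afterwards.  Total intensity is conserved away from the
  boundary; kernels below about 0.2 voxel degenerate to the identity.
* **Subsampling** is block-mean pooling (not decimation); the pooled mask
  voxel is true iff at least half its source block was inside the mask.
* **Tie-breaks.**  Breslow ties in all Cox computations; risk-group ties at
  linear predictor 0 go to the low-risk group; half-brain boundary voxels
  (zero dot product) go to the member's subset.

## Site-aware evaluation

Out-of-fold risk groups are compared with a Cox regression of the outcome
on the group, with the site as a Gaussian random intercept fitted by
penalized partial likelihood (`survival::coxph` + `frailty`).  With two or
fewer sites, or when the variance estimate hits the zero boundary, the
model falls back to site-stratified Cox, and to a plain Cox fit for a
single site (where it coincides with the unpenalized fit exactly).  The
per-voxel univariate map uses the Cox score test at $\beta=0$, whose $z$
equals the log-rank $z$ for binary features and untied event times; the
same routine backs the screening step.  Power calculations use the
Schoenfeld approximation
$\Phi\!\bigl(\sqrt{E\,p(1-p)}\,\lvert\log\text{HR}\rvert - z_{1-\alpha/2}\bigr)$;
this is one of several conventions in circulation and need not reproduce
other software's printed values.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` produces, per subject, four channels on a common grid
(default $16^3$ at 3 mm, mask = inscribed ellipsoid, ~1,800 in-mask
voxels): a smooth spatial base pattern, plus linear age and sex effects,
plus i.i.d. noise; modulated channels equal the unmodulated ones times a
subject-level warp factor, so the channels are correlated as real
modulated/unmodulated maps are.  A sparse set of signal voxels additionally
loads on a latent subject factor $u_i$; the true linear predictor sums the
signed per-voxel coefficients times the (pre-site-effect) signal-voxel
intensities, so the signal is recoverable yet spatially local.  Signal
voxels are planted as compact clusters (~6 adjacent voxels, one sign per
cluster), the pattern regional morphometric effects actually show;
isolated voxels with independent random signs would largely cancel under
smoothing and block pooling, leaving nothing for *any* method to recover.
Site effects are one additive offset and one multiplicative factor per
site.  Relapse times are exponential with hazard $r\,e^{\mathrm{lp}_i}$,
administratively censored at 24 months, with $r$ calibrated so the
expected event fraction is 20% (about the event yield a two-year
first-episode cohort provides); optional uniform dropout emulates loss to
follow-up.  Gaussian (age-like, $40 + 10\,\mathrm{lp} + N(0,5^2)$) and
binomial labels derive from the same linear predictor.  Defaults: 30
signal voxels in 5 clusters, coefficient magnitude 0.8, latent loading
0.05 intensity units, noise SD 0.05.  The coefficient magnitude was
calibrated once, by a sweep, to the smallest value at which the default
pipeline detects the planted risk group comfortably out of fold at
$n=240$ — the benchmark is specified as a detectable-effect design, the
synthetic analogue of powering a study for a target hazard ratio.

The generator does **not** emulate real anatomy, scanner physics,
registration error, non-linear age effects, or symptom-trajectory-based
relapse definitions (relapse is abstracted to a time and an indicator).
Passing tests therefore demonstrate the *statistical machinery* — leakage
discipline, harmonization, penalized estimation, ensembling, calibration of
the evaluation — not clinical accuracy on real cohorts.

## Problem sizes used by the test suite

The reference benchmark is $n=240$ subjects from 2 sites on the $16^3$
grid with ~20% events and the full default pipeline (4 channels,
$\sigma=4$ mm, triple subsampling, 18 half-brain members, 10 folds).  One
cross-validated run of this benchmark fits 180 ensemble members, each with
its own internal penalty selection, and takes a few minutes on one core;
the acceptance checks therefore run the full benchmark over a handful of
seeds, the null-calibration study over 40 seeds of a lighter no-ensemble
configuration, and the ensemble-ordering comparison over 8 seeds of a
diagnosis-like binomial benchmark.  That comparison benchmark is MRI-only
with two channels, double (6 mm) subsampling and a diffuse multi-cluster
signal: with ~380 voxel features against ~130 training subjects a single
fit is unstable enough for ensembling to matter, which is where the
half-brain ensemble's averaging pays and the subject bootstrap's
duplicated rows (which leak into its internal penalty selection) hurt.
On low-dimensional benchmarks the three ensemble settings coincide to
within noise.  These sizes are the package's own choices for routine
validation; all benchmarks are ordinary exported functions and can be
rerun at any scale.

## Known limitations

* Parametric EB shrinkage leaves a residual site effect when per-feature
  batch effects are nearly homogeneous (the shrinkage target then absorbs
  half of the per-feature sampling noise); this is a property of ComBat
  itself, shared with the reference implementation.
* The random-intercept Cox evaluation profiles a single site variance
  component; crossed or nested random effects are out of scope.
* The lasso uses a single penalty for clinical and voxel features; no
  elastic-net mixing or per-block penalty weighting.
* Half-brain plane angles and the behaviour of the original tool's
  unpublished internals (e.g. its exact 18 angles) cannot be replicated;
  ours are a documented deterministic construction.
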