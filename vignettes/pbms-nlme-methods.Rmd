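---
title: "Population-based model selection for radioiodine thyroid kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-based model selection for radioiodine thyroid kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbmsnlme)
```

## The problem

Pre-therapeutic dosimetry for radioiodine treatment of benign thyroid
disease requires the time-integrated activity (TIA) of ^131^I in the
gland: the integral over all time of the fraction of administered
activity retained, $\int_0^\infty a(t)\,dt$, in hours per unit
administered activity. The TIA is obtained by fitting a kinetic model to
sparse retention measurements (typically five time points over 2-120 h)
and integrating the fitted curve. The choice of fit function materially
changes the TIA, and different centres choosing different functions is a
known source of irreproducibility in molecular-radiotherapy dosimetry.

`pbmsnlme` implements a population-based answer: fit a systematic bank
of candidate kinetic functions to the *whole cohort at once* with a
non-linear mixed-effects (NLME) model, discard fits that fail objective
precision criteria, and let the corrected Akaike information criterion
(AICc) weigh the survivors. The per-patient TIAs then come from the
selected model's empirical Bayes parameter estimates.

## The model bank

All candidates are sums of exponentials (SOEFs) in which every exponent
also carries the physical decay constant
$\lambda_{phys} = \ln 2 / T_{1/2}$ of ^131^I ($T_{1/2} = 8.022$ d), so
that the biological and physical processes factor cleanly. The bank
spans two to four exponential terms with 3-6 adjustable parameters
(`model_bank()`): amplitudes $a_i \ge 0$ (fractions of administered
activity) and rates $\lambda_i \ge 0$ (1/h). Except for `a4c`, every
candidate satisfies $a(0) = 0$ — nothing is in the gland at the moment
of administration. Two candidates deserve names:

* `a3b`, the EANM standard-operational-procedure bi-exponential
  $\frac{\lambda_1}{\lambda_2+\lambda_1-\lambda_3}
  (e^{-(\lambda_3+\lambda_{phys})t} -
  e^{-(\lambda_1+\lambda_2+\lambda_{phys})t})$:
  first-order uptake from the blood pool and first-order clearance.
* `a4c`, the same function plus a blood-pool offset
  $a_1 e^{-(\lambda_1+\lambda_2+\lambda_{phys})t}$. It is the one
  candidate with $a(0) = a_1 \ne 0$: retention is measured as a
  neck-minus-thigh count-rate difference, and residual blood-pool signal
  in the neck field of view is not fully cancelled by the thigh
  measurement. `a4c` represents that residue explicitly.

The amplitude fraction of `a3b`/`a4c` is evaluated exactly as written;
a denominator $|\lambda_1+\lambda_2-\lambda_3| < 10^{-10}$ raises an
error in direct evaluation and is penalised (objective + $10^6$) during
fitting so the optimiser can retreat rather than crash.

Each model's TIA has a closed form — every term
$c\,e^{-(r+\lambda_{phys})t}$ integrates to $c/(r+\lambda_{phys})$ —
implemented in `soef_tia()` and verified against adaptive quadrature to
1e-8 relative tolerance in the test suite.

## The mixed-effects model

Patient $i$'s parameter vector is
$P_i = \mathrm{TVP} \cdot \exp(\eta_i)$ with
$\eta_i \sim N(0, \mathrm{diag}(\omega^2))$: fixed effects (typical
values) with log-normal inter-individual variability, which keeps all
parameters positive and makes $\omega$ interpretable as an approximate
coefficient of variation. Residual error is proportional by default,
$y = f \cdot (1+\varepsilon)$, $\varepsilon \sim N(0, \sigma^2)$, with
additive, combined ($\sigma_{add}^2 + \sigma_{prop}^2 f^2$) and
exponential (additive-normal on log observations) variants available.
The variants follow the standard popPK conventions; the proportional
variance uses the model prediction, not the observation. For a model
with $p$ structural parameters the fitted-parameter count is
$K = 2p + 1$ ($p$ fixed effects, $p$ variances, one residual variance).

### Estimation

The marginal likelihood integrates over $\eta_i$; `pbmsnlme` uses the
Laplace approximation: an inner damped Gauss-Newton optimisation finds
each patient's conditional mode $\hat\eta_i$, and the curvature
correction uses a full finite-difference Hessian of the joint negative
log density at that mode (implemented in C++). All Gaussian
normalisation constants are included, identically for every model, so
AICc *differences* are invariant to the convention; absolute objective
values are engine-specific and are never compared across software. The
test suite pins the approximation against adaptive Gauss-Hermite
quadrature (64 nodes) on small instances for all four error models,
requiring agreement within 0.5 on the $-2\log L$ scale.

The outer search runs over $\log \mathrm{TVP}$, $\log \omega^2$,
$\log \sigma^2$ (positivity without constrained solvers), with
finite-difference gradients whose step shrinks with the current residual
SD so the step stays inside the likelihood valley even on nearly
noise-free data. Multi-start: starting rates are drawn log-uniform on
$[10^{-4}, 1]$ 1/h, amplitudes on $[10^{-3}, 1]$, $\omega$ starts at 0.5
and $\sigma$ at 0.1; every start gets a capped exploratory run and the
best few candidates are polished to convergence (restarting until the
objective is stable within $10^{-6}$ relative — with numerical gradients
the raw optimiser return code alone is too pessimistic). The converged
fit with the lowest objective wins (ties break to the lowest start
index) and receives one final refinement pass against a tight
inner-tolerance objective, so the optimum handed to the covariance step
is as quiet as the surface allows. The reference analysis used 1000 starts; `fit_nlme()` accepts any
budget, and the package's own end-to-end checks use 50-100 starts, which
on this likelihood reach the same optimum in a few minutes on one core.

### Uncertainty

The covariance of the estimates is twice the inverse finite-difference
Hessian of the objective at the optimum, taken on the log scale with a
step (0.02) wide enough to average over the sub-1e-5 roughness that the
inner optimisation leaves on the surface. Delta-method RSEs follow: for
a log-scale parameter, the RSE of the natural estimate is the log-scale
SE — halved for $\omega$ and $\sigma$, which are reported on the SD
scale while the search runs on variances. Sampling importance
resampling (`sir_uncertainty()`) provides an independent check: draws
from the multivariate-normal proposal at the estimate are re-weighted by
the true likelihood ratio and resampled; the suite requires the two
routes to agree within 30% on a well-behaved fit.

## The goodness-of-fit gate and selection

A fit enters model selection only if (strict inequalities, boundary
fails): every fixed-effect RSE < 0.3, every random-effect RSE (inter-
and intra-individual) < 0.5, the maximum absolute off-diagonal
correlation of the estimates < 0.8, and the fit converged with a usable
covariance. These are the published "precise" criteria; gated-out models
carry no Akaike weight.

The published procedure additionally requires that "visual inspection of
the fitted curves is acceptable". As a reproducible stand-in,
`goodness_of_fit_gate()` computes, per nominal sampling-time bin, a
one-sample z statistic of the individual (empirical-Bayes) weighted
residuals and fails the fit if any bin mean is shifted from zero beyond
a Bonferroni-adjusted threshold (familywise level 0.01 across bins).
Population-prediction residuals were considered and rejected for this
check: they are dominated by inter-individual variability, so their
bin means are far noisier than $1/\sqrt{n}$ and any fixed threshold on
them either never fires or always fires. The check is reported
separately and can be disabled
(`gate_thresholds(residual_trend = FALSE)`); the published gate
outcomes are reproduced by the RSE and correlation criteria alone.

Selection over the gate-passing set $F$ uses
$AICc = -2\ln\hat L + 2K + 2K(K+1)/(N-K-1)$,
$\Delta_{px} = AICc_{px} - AICc_{min}$, and weights
$w_{px} = e^{-\Delta_{px}/2} / \sum_{j \in F} e^{-\Delta_j/2}$
(minimum subtracted before exponentiation for stability). AICc is
reported unrounded; ties within $10^{-6}$ break to fewer parameters.

## The individual-fit comparator

The EANM SOP route fits `a3b` to each patient separately by maximum
likelihood under the proportional error model with one *shared*
residual variance, ML-profiled across patients by alternating patient
fits with variance updates. The shared variance keeps the pooled
objective on the same likelihood scale as the population fits, so the
two methods meet on one AICc axis with $K = 3 \times$ patients (219 for
the published cohort) — whether the original analysis shared or
per-patient-profiled the variance is unstated, and only the AICc
arithmetic is checked against printed values. Individual fitting
requires at least $p+1$ observations per patient ($K_{max} = N - 1$).

## Synthetic populations

The raw patient data are not public, so `simulate_population()`
regenerates the study design exactly: 73 patients sampled at 2, 6, 24,
48 h and a final sample at 96 h (53 patients) or 120 h (20 patients),
the first schedule-a patient lacking the 6-h sample, N = 364. Default
generating parameters are the published `a4c` population estimates:
fixed effects $a_1 = 7.1\times10^{-2}$,
$\lambda_1 = 7.9\times10^{-2}$/h, $\lambda_2 = 6.7\times10^{-2}$/h,
$\lambda_3 = 1.2\times10^{-3}$/h; inter-individual CVs 0.79, 1.1, 0.51,
1.0; proportional residual SD $4.8\times10^{-2}$.

Two documented choices:

* **CV to omega.** Printed inter-individual variability is a CV; the
  log-normal model's exact relation $\omega = \sqrt{\ln(1+CV^2)}$ is the
  default mapping, keeping generation and reporting self-consistent.
  Whether the printed CVs are in fact $\omega$ itself (a common
  reporting shortcut) is unknowable from the publication; both readings
  are supported (`cv_mode = "omega"`), and the recovery checks use only
  fixed effects and $\sigma$, which the ambiguity does not touch.
* **Negative draws.** A proportional draw can go non-positive at small
  predictions; the residual is redrawn (preserving the nominal residual
  distribution) rather than truncated, and redraws are counted in the
  output's `redraws` attribute.

What the generator deliberately does not emulate: the NaI count-rate
acquisition chain (background, dead time, thigh subtraction), model
misspecification (the truth *is* `a4c`), covariate structure, and
non-log-normal parameter distributions. Passing recovery and calibration
checks on these populations therefore demonstrates that the estimation
and selection machinery works under the model's own assumptions — not
that `a4c` is the right model for any new cohort.

## Validation diagnostics

`vpc()` simulates replicate cohorts from the fitted model under the
original design and compares observed 5th/50th/95th percentiles per
nominal time bin with the simulated percentile bands (binning at the
design times; no binning algorithm is needed for nominal-time
sampling). `npde()` computes normalised prediction distribution errors:
per patient, observed and simulated vectors are decorrelated with the
inverse symmetric square root of the simulated covariance, each
observation's rank among its simulations (ties broken by seeded uniform
jitter of one rank width) maps through the standard-normal quantile.
Defaults are 500 (VPC) and 1000 (NPDE) replicates. Under a correct
model the NPDEs are approximately standard normal; the suite checks
mean within $\pm 0.1$ and variance in $[0.8, 1.2]$ at N = 364.
`error_model_sweep()` refits under the alternative residual models and
reports TIA relative deviations against the proportional reference,
mirroring the published sensitivity analysis (which found the choice
negligible).

## Numerical choices, degenerate inputs, limitations

* A random-effect variance below $10^{-12}$ drops that dimension from
  the Laplace integral; the limit is continuous, and `omega2 = 0`
  reproduces the fixed-effects-only likelihood exactly.
* Proportional-error predictions with $|f| < 10^{-12}$, non-finite
  structural values, and non-positive predictions under the exponential
  model are penalised, not fatal.
* Fractions must lie in $(0, 1.5]$: mild noise above 1 is physical
  (measurement), gross values are schema errors.
* Problem sizes in the shipped checks (50-100 starts, 8-14-patient unit
  fixtures, 200-1000 diagnostic replicates) are the package's chosen
  defaults for a single-core desk run; all are arguments.
* The Laplace approximation shares the known limitations of its class:
  with very sparse per-patient data and large $\omega$, empirical Bayes
  estimates shrink heavily and per-patient TIAs inherit that shrinkage.
  The published discussion makes the same caveat; covariate modelling,
  the suggested remedy, is out of scope here.
* Absolute objective values are not comparable across engines (additive
  constants differ); only AICc differences and weights are.
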