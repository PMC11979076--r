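# pbmsnlme

Population-based model selection with non-linear mixed effects for
^131^I thyroid retention kinetics.

## The problem

Pre-therapy dosimetry for radioiodine treatment of benign thyroid
disease hinges on the time-integrated activity (TIA) of ^131^I in the
gland, `∫₀^∞ a(t) dt`, where `a(t)` is the fraction of administered
activity retained at `t` hours. The TIA comes from fitting a kinetic
function to a handful of retention measurements per patient and
integrating the curve — and the choice of function materially changes
the answer. The EANM standard operational procedure prescribes one
bi-exponential fitted per patient; different centres choosing different
functions is a recognised reproducibility problem.

`pbmsnlme` fits a systematic bank of nine sum-of-exponential candidates
(3–6 adjustable parameters, every exponent carrying the physical decay
constant `λ_phys = ln 2 / 8.022 d`) to the *whole cohort at once* with a
non-linear mixed-effects model

    P_i = TVP · exp(η_i),   η_i ~ N(0, diag(ω²)),
    y   = f(t; P_i) · (1 + ε),   ε ~ N(0, σ²),

estimated by a multi-start Laplace engine (C++ core). Fits must pass
precision criteria (fixed-effect RSE < 0.3, random-effect RSE < 0.5,
max |off-diagonal correlation| < 0.8, plus an automated residual-trend
check) before entering selection by the corrected Akaike information
criterion,

    AICc = −2 ln L̂ + 2K + 2K(K+1)/(N−K−1),
    w_px = exp(−Δ_px/2) / Σ_{j∈F} exp(−Δ_j/2),

with weights normalised over the gate-passing set `F`. Per-patient TIAs
follow in closed form from the selected model's empirical Bayes
estimates. The package also implements the per-patient EANM comparator
(`fit_individual_pooled()`, `K = 3 ×` patients on one shared AICc
scale), TIA comparison metrics (RD, RMSE, MAPE), and internal
validation (VPC, NPDE, SIR parameter uncertainty, residual-error-model
sweep). A design-faithful synthetic-population generator (73 patients,
N = 364, published generating values) stands in for the study's
non-public patient data.

## Worked example

```r
library(pbmsnlme)

pop <- simulate_population(seed = 42)   # 73 patients, N = 364
fit <- fit_nlme(pop, "a4c", n_starts = 50, seed = 7)
glance(fit)
#> # A tibble: 1 × 9
#>   model_id error_model      K n_obs n_patients     of   aicc converged
#>   <chr>    <chr>        <int> <int>      <int>  <dbl>  <dbl> <lgl>
#> 1 a4c      proportional     9   364         73 -1197. -1178. TRUE
tidy(fit)
#> # A tibble: 9 × 5
#>   term      type     estimate     cv    rse
#>   <chr>     <chr>       <dbl>  <dbl>  <dbl>
#> 1 tvp_a1    fixed     0.0632  NA     0.106
#> 2 tvp_l1    fixed     0.0831  NA     0.112
#> 3 tvp_l2    fixed     0.0675  NA     0.0647
#> 4 tvp_l3    fixed     0.00155 NA     0.132
#> 5 omega2_a1 iiv       0.735    0.846 0.0879
#> 6 omega2_l1 iiv       0.935    1.18  0.0852
#> 7 omega2_l2 iiv       0.473    0.501 0.108
#> 8 omega2_l3 iiv       0.857    1.04  0.120
#> 9 sigma     residual  0.0416  NA     0.0660

tias <- tia_per_patient(fit)
summary(tias$tia_h)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   11.77   61.15   91.08   95.74  129.17  197.65
```

The fixed effects recover the generating values (`a1 = 0.071`,
`λ1 = 0.079`, `λ2 = 0.067`, `λ3 = 0.0012`, `σ = 0.048`) within their
sampling uncertainty; the `rse` column is the delta-method relative
standard error from the estimate covariance; the `cv` column re-expresses
the inter-individual SD `ω` as a log-normal coefficient of variation.
`tia_h` is each patient's time-integrated activity in hours per unit
administered activity — multiply by the administered activity for the
dose-determining quantity.

Full selection over the bank:

```r
sel <- run_pbms(pop, n_starts = 100, seed = 1)   # ~10-15 min on one core
tidy(sel)          # per-model gate outcome, AICc, Δ, Akaike weight
autoplot(sel)      # weight bar chart
```

and the pipeline wrapper `run_pipeline()` chains simulation → fitting →
gate → selection → TIAs → individual-fit comparison → diagnostics with
one top-level seed and a JSON/CSV report bundle.

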