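---
title: "Statistical methods for floating-tablet dissolution analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for floating-tablet dissolution analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floatdoe)
```

## The problem

Gastro-retentive sustained-release tablets — here a non-effervescent
floating matrix tablet of metformin HCl built from cetyl alcohol (floating
agent) and HPMC K15M (gel-forming release retardant) — are optimized
against a marketed reference product by comparing in vitro dissolution
profiles. The workflow this package implements has four statistical
layers:

1. **Profile similarity.** The Moore–Flanner similarity factor
   $f_2 = 50\log_{10}\{[1 + \tfrac1P\sum_i(\mu_{ti}-\mu_{ri})^2]^{-1/2}\times100\}$
   compares mean test and reference release at $P$ time points; $f_2 > 50$
   is the conventional similarity criterion. Because the sample $f_2$ is a
   nonlinear statistic of noisy means, we also report the
   variance-penalized estimate $E(f_2)$ and nonparametric bootstrap
   intervals, and require the *interval lower bounds* — not just the point
   estimate — to clear the cutoff.
2. **Release kinetics.** Zero-order, first-order, Higuchi and
   Korsmeyer–Peppas models are fitted to the mean profile; the power-law
   exponent $n$ classifies the transport mechanism (Fickian below 0.45
   for this geometry).
3. **Design of experiments.** A two-level full factorial screens cetyl
   alcohol mass $A$ (mg) and HPMC proportion $B$ (%); a face-centered
   central composite design fits linear/quadratic response-surface models
   of release at 60, 240 and 480 min, validated externally by RMSEP, and
   the fitted equations are inverted to find the minimum HPMC content
   whose predicted $f_2$ exceeds 50.
4. **Formulation accounting.** Tablet mass balance (fixed drug and cetyl
   masses, HPMC and lubricant as percentages of total mass) plus
   swelling and matrix-erosion percentages from wet/dry weights.

Raw per-unit dissolution tables for such studies are rarely published, so
the package ships a synthetic-data generator that reproduces the study
conditions and makes every downstream stage testable end to end.

## The synthetic-data generator

`simulate_profiles()` emulates one dissolution run: `n_units` tablets
(default 12, the regulatory bootstrap-$f_2$ sample size) sampled on the
10-point grid 15–1440 min. The mean curve is the power law
$Q(t)=\min(\mathrm{cap},\,k\,t^{n})$; the default $k = 4.349$,
$n = 0.4717$ is the two-point log–log solution through (60 min, 30%) and
(480 min, 80%), i.e. a reference product releasing roughly 30/60/80% at
60/240/480 min (`kp_solve_targets()`). Between-tablet variability is
additive Gaussian noise per time point (default SD 2 percentage points, a
typical HPLC-assayed dissolution spread at $n=12$); each unit's series is
then monotonized by a running maximum — cumulative release cannot
decrease — and clipped to $[0,\mathrm{cap}]$.

What this emulates: independent units, homoscedastic noise, a smooth
monotone mean. What it does not: correlated within-unit errors,
heteroscedasticity near the plateau, tablet failures, or
apparatus-specific effects. Passing tests therefore demonstrate the
correctness of the *statistical machinery* under clean conditions, not
robustness to every pathology of real dissolution data. The
monotonization step introduces a small positive bias (well under 0.2
percentage points at the default noise level, as the convergence test
shows) wherever consecutive mean-curve increments are comparable to the
noise SD.

`simulate_doe_responses()` fills any design with responses from
actual-scale equations plus Gaussian noise; with zero noise it reproduces
the equations exactly, which is how the model-recovery tests are built.
`simulate_swelling()` uses a saturating-exponential water uptake
(rapid early swelling, plateau within a day) and strictly linear dry-mass
erosion, the qualitative behaviour of HPMC matrices.

## Numerical and design choices

* **Logarithm base.** $f_2$ uses base 10 throughout; the familiar
  50–100 similarity range only arises in base 10.
* **$E(f_2)$ grouping.** The variance penalty $(s_t^2+s_r^2)/n$ enters
  *inside* the $1/P$ average (default `pool_p = TRUE`), matching the
  per-time-point expectation
  $E[(\chi_t-\chi_r)^2] = (\mu_t-\mu_r)^2 + (\sigma_t^2+\sigma_r^2)/n$.
  The typeset form of this estimator is ambiguous in parts of the
  literature, so the alternative grouping is available as a switch.
* **Bootstrap resampling unit.** Whole tablets (entire time vectors) are
  resampled with replacement, independently within test and reference and
  preserving each $n$ — never per-time-point resampling, which would
  destroy within-tablet correlation. Per replicate the test indices are
  drawn before the reference indices, so one seed pins the whole stream.
* **Quantile rule.** Percentile bounds are empirical-CDF (type 1) order
  statistics at ranks $\lceil B\alpha/2\rceil$ and
  $\lceil B(1-\alpha/2)\rceil$; at $B=500$ this avoids interpolation
  ambiguity. BCa bounds apply the same rule at the adjusted levels.
* **BCa construction.** $z_0 = \Phi^{-1}(\#\{f_2^{*b} < f_2\}/B)$ with
  ties counting one half; acceleration $a$ from a delete-one jackknife
  over the *combined* unit list (delete one test **or** one reference
  unit, $n_t+n_r$ replicates),
  $a = \sum(\bar\theta-\theta_i)^3/[6(\sum(\bar\theta-\theta_i)^2)^{3/2}]$
  — the conventional Efron construction. If every bootstrap replicate is
  identical the PI collapses to that constant and BCa is flagged
  degenerate ($z_0$ undefined) rather than fabricated.
* **Equivalence rule.** `assess_equivalence()` requires the sample $f_2$,
  the PI lower bound *and* the BCa lower bound to exceed the cutoff
  strictly. This is deliberately conservative: a formulation whose mean
  $f_2$ is just above 50 but whose interval dips below is eliminated.
* **Kinetics conventions.** Zero-order and Higuchi are fitted through the
  origin; first-order fixes the intercept at $\ln 100$ (complete load);
  Korsmeyer–Peppas is fitted on $\log_{10}(Q/100)$ vs $\log_{10} t$
  restricted to $0 < Q \le 60\%$, the early-time window where the power
  law is valid. $R^2$ is reported on each model's own fitting scale
  (uncentered for through-origin fits, the same convention `lm()`
  reports), not back-transformed; model selection maximizes $R^2$ with a
  fewer-parameters tie-break. Note the scale asymmetry this implies: the
  generator's $k$ is percent·min$^{-n}$, while the fitted power-law $k$
  is on the $M_t/M_\infty$ fractional scale.
* **Coded vs actual DoE models.** OLS is performed on coded levels
  $a = (A-\bar A)/(\Delta A/2)$; actual-unit coefficients come from exact
  algebraic substitution of the coding transform, so both forms agree at
  every design point to machine precision. Published tables that round
  the two forms independently cannot have this property; this package
  guarantees internal consistency instead of matching two rounded forms
  simultaneously. ANOVA is the standard OLS $t$/$F$ testing, adequate
  because the coded FFD/CCF designs are (near-)orthogonal.
* **Threshold solver.** `solve_hpmc_threshold()` bisects the predicted
  $f_2(B) - \mathrm{cutoff}$ at fixed $A$ to $10^{-4}$ percentage points,
  erroring with both bracket values when no sign change exists. With the
  packaged default linear equations at $A = 150$ mg against the
  (30, 60, 80) reference the threshold is about 16.9% HPMC.
* **Prediction clipping.** Predicted release is clipped to $[0, 100]$
  only at prediction time (flagged), never during fitting;
  out-of-range compositions are computed but flagged as extrapolations.
* **Mass-balance basis.** Both HPMC and magnesium stearate are
  percentages of the *total* tablet mass, so
  $\mathrm{total} = (\mathrm{drug}+\mathrm{cetyl})/(1-h-m)$. This basis
  reproduces the published formulation weights to within ordinary
  rounding (0.2 mg); residual sub-0.2 mg differences in printed tables
  are tolerated, not "corrected".

## Problem sizes in the test suite

The suite exercises the machinery at the study's own scale: 12+12 units,
$B = 500$ bootstrap replicates, 90% intervals. The interval-coverage
property uses 200 simulated paired datasets at noise SD 2 against the
closed-form population $f_2$ of the generating curves (nominal 90%
coverage, checked within ±7%); exponent-recovery properties use 100
seeded curves with $n \in [0.2, 0.9]$. Bootstrap stability is checked by
comparing $B=500$ against $B=2000$ (the bootstrap mean moves by well
under 0.5 $f_2$ units). A single global seed convention (documented
default 20210808 for ad-hoc exploration; every test and script passes
seeds explicitly) keeps all of this reproducible.

## Known limitations

* The generator's additive-then-monotonized noise is simpler than real
  between-tablet variability; coverage statements are exact only for
  this noise model.
* $E(f_2)$ is asymptotically unbiased, not exactly unbiased, and can be
  a poor summary at very small $n$ or very large variances.
* BCa intervals depend on the jackknife scheme; other schemes
  (delete-one *pairs*, parametric accelerations) give slightly different
  bounds. The combined-list delete-one scheme used here is stated
  explicitly so results are reproducible.
* The kinetics fits are on the mean profile; unit-level fitting (and the
  resulting uncertainty in $n$) is out of scope.
* No desirability-based multi-response optimization, no Box–Cox
  transforms, no blocking structures; the response-surface layer covers
  exactly the two-factor linear/quadratic case.

## A worked run

```{r example, fig.width = 6, fig.height = 4}
ref <- simulate_profiles(unit_sd = 2, seed = 101, product_id = "REF")
p <- kp_solve_targets(c(60, 480), c(33, 82))
test <- simulate_profiles(k = p$k, n_exp = p$n_exp, unit_sd = 2,
                          seed = 102, product_id = "TEST")

res <- bootstrap_f2(test, ref, time_points = c(60, 240, 480),
                    B = 500, seed = 103)
res
assess_equivalence(res)

fits <- fit_release_models(summarize_profile(test)$time_min,
                           summarize_profile(test)$mean_release)
fits
classify_mechanism(fits$n[fits$model == "korsmeyer_peppas"])

models <- response_models_from_coeffs()
predict_dissolution(models, A = 150, B = 17)
solve_hpmc_threshold(models, A = 150)
tablet_mass(500, 150, 17, 5)
```
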