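---
title: "Methods: population pharmacokinetics and dose optimization of vancomycin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population pharmacokinetics and dose optimization of vancomycin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

vancopk implements a complete population-pharmacokinetic workflow for
intermittent intravenous vancomycin in adults whose renal function ranges
from severe impairment to augmented renal clearance (ARC, CLcr >= 130
mL/min): deterministic kinetics, nonlinear mixed-effects estimation,
model qualification, and Monte Carlo dose optimization.

## Structural model

Disposition is linear and two-compartmental with zero-order infusion
input. With micro-constants $k_{10} = CL/V_c$, $k_{12} = Q/V_c$,
$k_{21} = Q/V_p$, the hybrid rate constants $\alpha,\beta$ solve
$\lambda^2 - (k_{10}+k_{12}+k_{21})\lambda + k_{10}k_{21} = 0$, and every
concentration is the superposition of closed-form infusion responses: a
finite infusion is the difference of two never-ending infusions started at
the infusion's start and stop. Setting $Q = 0$ gives the one-compartment
model by an explicit branch, and when $\alpha$ and $\beta$ coincide to
within a relative $10^{-9}$ the code switches to the analytic
repeated-root limit (the $t e^{-\lambda t}$ disposition term) rather than
evaluating a catastrophically cancelling difference. The closed form is
verified against stiff ODE integration (deSolve, lsoda, tolerances
$10^{-11}$) to a relative $10^{-6}$ in the test suite.

Steady-state exposures never rely on long simulation: AUC24 is exactly
(daily dose)/CL for linear kinetics, and the trough comes from the
geometric-series accumulation of each exponential term,
$1/(1-e^{-\lambda\tau})$ per eigenvalue; long-run simulation survives only
as a test oracle for both.

## Covariate and stochastic model

Typical clearance is a saturable (Hill) function of the Cockcroft-Gault
creatinine clearance,
$$CL = CL_{max}\,\frac{CLcr^{s}}{CG_{50}^{s} + CLcr^{s}},$$
strictly increasing, half-maximal exactly at $CG_{50}$ and bounded by
$CL_{max}$; this is the mechanism behind the clinically important plateau
of dose requirements in ARC. Typical central volume takes separate values
for ward and intensive-care patients (the ICU value is ~4.5-fold the ward
value in the reference estimates, a 3.5-fold increase). Random effects are
lognormal on CL and $V_c$ ($P_i = P_{pop}e^{\eta}$, $\eta \sim N(0,
\omega^2)$) and the residual model is proportional, $y = f(1+\epsilon)$,
$\epsilon \sim N(0, \sigma^2)$.

One labelling ambiguity is resolved deliberately: the reference residual
variance 0.0466 is sometimes tabulated under an "additive" heading, but
the generating equation is a constant-coefficient-of-variation
(proportional) model; vancopk treats 0.0466 as $\sigma^2$ of the
proportional model throughout.

Serum creatinine is accepted in mg/dL or umol/L with a mandatory unit tag
(conversion 88.4 umol/L per mg/dL) because silently mixed units are a
classic source of corrupted renal-function covariates; when a subject has
several creatinine records the package uses the admission mean of the
per-record Cockcroft-Gault values.

## Key tunable parameters

| parameter | unit | default | why |
|---|---|---|---|
| `cl_max` | L/h | 5.58 | theoretical maximum clearance |
| `cg50` | mL/min | 93.8 | CLcr at half-maximal clearance |
| `s` | - | 1.5 | steepness of the saturable curve |
| `vc_non_icu`, `vc_icu` | L | 8.02, 35.7 | fluid-loading/permeability shift in ICU |
| `q`, `vp` | L/h, L | 2.66, 36.8 | peripheral distribution |
| `omega2_cl`, `omega2_vc` | - | 0.0771, 0.223 | inter-individual variances (log scale) |
| `sigma2` | - | 0.0466 | proportional residual variance |
| infusion duration | h | 1 (2 if dose >= 1500 mg) | rate-limited infusion practice; configurable per event |

# Estimation: FOCE-I

The objective is the first-order conditional approximation with
interaction to $-2\log L$. Per subject $i$:

1. the conditional mode $\hat\eta_i$ of the joint density is found by a
   Newton search with finite-difference derivatives and backtracking line
   search, restarted statelessly at $\eta = 0$ on every outer iteration
   (reproducibility beats warm-start speed here);
2. the prediction is linearized at $\hat\eta_i$,
   $f(\eta) \approx f(\hat\eta) + F(\eta - \hat\eta)$, with
   $F = \partial f/\partial\eta$ by central differences;
3. the residual variance is evaluated at the mode,
   $R = \sigma^2 f(\hat\eta)^2$ — the "interaction" term;
4. the subject's contribution is the linear-Gaussian marginal
   $\log|V| + r^\top V^{-1} r + n_i\log 2\pi$ with
   $V = F\,\Omega\,F^\top + R$ and $r = y - f(\hat\eta) + F\hat\eta$.

The $n\log 2\pi$ constant is kept so the objective is directly comparable
to an exact marginal likelihood; the adaptive Gauss-Hermite oracle in the
test suite (mode-centred, Hessian-scaled, 15 nodes per dimension) agrees
within 1 unit on 10-subject cohorts. The outer problem minimizes the
objective over log-transformed fixed effects and variance components
(slopes of linear/exponential covariate forms stay on the identity scale)
with `nlminb`, relative tolerance $10^{-8}$, after a naive-pooled prefit
(random effects fixed at zero) that turns generic starting values into
good initials. Relative standard errors come from the inverse
finite-difference Hessian at the optimum; on the log scale the standard
error is already an approximate coefficient of variation. Convergence is
the optimizer's own criterion; inner-search failures are counted and
reported rather than silently absorbed.

Degenerate inputs are handled explicitly: subjects without observations
are excluded from fitting with a warning, predictions are floored at
$10^{-10}$ mg/L before logs, non-finite parameter proposals get a large
penalty rather than crashing the line search.

## Model selection

`compare_structures()` fits one- and two-compartment models and selects
the lower AIC ($AIC = OFV + 2k$). `compare_cl_forms()` fits the saturable,
linear ($1+\theta(x-\tilde x)$), exponential and power clearance-CLcr
forms, each centred at the dataset median $\tilde x$, and tabulates OFVs.
`covariate_search()` is the classical forward-inclusion /
backward-elimination procedure: a candidate enters when its OFV drop
exceeds the $\chi^2_{0.05}$ critical value for the parameters it adds
(3.84 for one), and survives elimination only when removal raises the OFV
by more than the $\chi^2_{0.001}$ value (10.83 for one). The saturable
form adds two parameters, so its thresholds are df-scaled (5.99/13.82) —
the single-parameter thresholds would be anti-conservative. Every tested
step lands in an audit trail; failed candidate fits are logged and treated
as not significant.

# The synthetic cohort

The raw hospital TDM data behind the reference analysis are confidential,
so `generate_cohort()` emulates their design. What it reproduces: 209
adults, 39.2% ICU, 60.3% male, age 66.0 +/- 16.4 y and weight 63.4 +/-
12.9 kg (truncated normals, inverse-CDF sampling so the RNG stream length
is deterministic), creatinine clearance spanning 18.4-390.7 mL/min, sparse
sampling (49.3/23.9/13.9/12.9% of subjects contributing 1/2/3/4+ levels)
concentrated 5-12 h after the start of an infusion, and q12h infusion
histories. Choices the source design does not pin down, made once and
documented here:

- **CLcr is drawn log-uniformly** over its range, not normally: a normal
  centred at the median would leave the ARC tail nearly empty, and the
  ARC tail is the scientific point. Serum creatinine is back-solved from
  the target CLcr so the covariate is internally consistent.
- **Dosing policy**: the source reports only a median daily dose (~1875
  mg). Synthetic subjects get a clinician-like heuristic — 15 mg/kg q12h
  scaled by renal band (0.25/0.5/1/1.3 below 30, below 60, below 130, and
  at/above 130 mL/min), rounded to 250 mg and clipped to 250-2500 mg per
  dose, 4-8 doses.
- **The "4+" sampling class** draws 4-6 levels uniformly, which makes the
  expected total ~424 observations for 209 subjects.
- **Sampling times** are offsets from the start of the final infusion,
  drawn from the design's window distribution (0.5-3, 3-5, 5-12, 12-24,
  24-48 h), so the time-after-dose distribution matches by construction.
- Observations are $f(1+\epsilon)$ floored at a configurable assay LLOQ
  (default 0 = no censoring).

All draws come from a single seeded stream in a fixed documented order, so
cohorts regenerate byte-identically.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: TDM feedback (real doses respond to measured
levels, creating covariate-dose dependence), time-varying renal function
within an admission, correlated covariates beyond the Cockcroft-Gault
identity, assay censoring patterns, and any diagnosis mix beyond marginal
shock/multiple-organ-failure rates kept as metadata. Parameter-recovery
results on this cohort demonstrate estimator correctness under the stated
design, not robustness to clinical confounding.

# Dose optimization

`simulate_pta()` draws creatinine clearance uniformly within a stratum
(the within-stratum distribution is not specified by any source; uniform
is the explicit, swappable assumption, and the semianalytic oracle
`pta_semianalytic_auc()` — a normal-CDF integrand integrated over the
stratum — makes it auditable), applies lognormal inter-individual
variability, and evaluates the steady-state metric without residual assay
error: the target concerns true exposure, not measurement. Strata follow
the conventional renal bands 15-29 through 150-179 plus a merged >= 180
band (clearance is nearly saturated there, so finer 30-unit bands behave
alike); the grid is 250-2500 mg by 250 mg at intervals 8/12/24 h.

`recommend_regimens()` evaluates the whole grid per stratum on one shared
set of simulated subjects (common random numbers). This has a visible
consequence: because steady-state AUC24 is daily dose over clearance,
regimens with equal daily dose attain the AUC24 target *identically*, and
ties are exact rather than decided by simulation noise. Ties are broken
toward the smaller dose per administration first (practical infusion-rate
and tolerability considerations favour splitting large daily doses), then
fewer administrations, then lower daily dose. Equal-daily-dose rows in the
recommendation table are therefore interchangeable on the AUC criterion,
and the table should be read per daily dose. Trough-target attainment
depends on the full disposition model, so it is computed separately for
ICU and non-ICU populations.

# Numerical choices, in one place

- repeated-root switch at $|\alpha-\beta|/\alpha < 10^{-9}$; analytic
  limit form, no epsilon perturbation;
- inner Newton: finite-difference step $10^{-4}$, gradient tolerance
  $10^{-7}$, at most 60 iterations, ridge-regularized steps, steepest
  descent fallback;
- outer `nlminb`: relative tolerance $10^{-8}$, iteration cap 500;
  pooled prefit capped at 300 iterations;
- initial estimates: generic ($CL$ 3 L/h scale, $CG_{50}$ at the covariate
  median, $s = 1$, volumes 12-30 L, $\omega^2 = 0.1$, $\sigma^2 = 0.05$)
  refined by the pooled stage;
- VPC: 8 equal-count time-after-dose bins (configurable), percentiles
  5/50/95, 90% simulation intervals;
- bootstrap success = converged with finite relative standard errors;
  percentile 2.5/97.5 intervals over successful replicates.

# Problem sizes

The acceptance-level checks run at full scale: Monte Carlo attainment at
$n = 10{,}000$ per stratum/regimen and parameter recovery as the median of
five independent 209-subject cohorts. Unit and property tests use sizes
chosen for tight feedback loops: bootstrap behaviour on 8-10 replicates,
VPC self-coverage on 200 simulated replicates, covariate-search recovery
and type-I behaviour on 50-60 subjects with a deliberately rich sampling
design (six levels per subject), and the null-covariate check on three
seeded replicates. These sizes are the package's testing choices; the
functions default to the conventional large values (1000 bootstrap
replicates, 1000 VPC simulations, 10,000 PTA draws).

# Known limitations

- FOCE-I is an approximation; no SAEM or importance-sampling estimator is
  provided, and no inter-occasion variability.
- Relative standard errors use the inverse Hessian on the log scale; they
  can differ from sandwich or bootstrap uncertainty, and eta-shrinkage is
  not reported.
- Kinetics are linear: no saturable elimination, no renal-replacement or
  acute-kidney-injury dynamics (such patients are outside the model's
  support), and creatinine clearance is collapsed to its admission mean.
- The recommendation table optimizes marginal attainment for a typical
  population; it is an initial-dosing tool, not a Bayesian
  individualization engine.
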