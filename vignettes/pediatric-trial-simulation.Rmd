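---
title: "Model-informed design of a pediatric spironolactone PK trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-informed design of a pediatric spironolactone PK trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spirped)
```

## The problem

Spironolactone (SPIR) is a potassium-sparing diuretic that has been given to
children off-label for decades, without an approved liquid formulation or
pediatric dosing guidance. An oral suspension now exists for adults, and a
pediatric PK trial in children 2 to <17 years with edema (heart failure or
liver cirrhosis) has to pick doses and blood-sampling times before any
pediatric concentration data exist. `spirped` implements the quantitative
machinery for that design problem: an adult population PK model for SPIR and
its active metabolite canrenone (CAN), allometric bridging to pediatric body
weights, what-if scenario modifiers for cirrhosis and food, Monte Carlo dose
selection against adult reference exposures, and evaluation of a windowed
sparse sampling design.

## Structural model

Both analytes follow linear two-compartment disposition. An oral dose enters
a depot with first-order rate `ka` (1/h) after a lag `alag1` (h). SPIR is
cleared by two parallel apparent routes: a non-CAN route `cl` and metabolic
conversion to CAN `clm1`, mixed by the fraction metabolized `fm` so that

    CLtot = cl * (1 - fm) + clm1 * fm.

The CAN formation flux is `fm * clm1 * C_spir`, and CAN is then cleared with
`clm` from its own central volume `v4` with peripheral exchange (`q1`, `v5`);
SPIR has the analogous pair (`q`, `v3`) around its central volume `v2`. All
clearance and volume parameters are *apparent* (conditioned on the unknown
oral bioavailability F, which is not identifiable without intravenous data);
consequently a bioavailability change is algebraically identical to scaling
the administered amount, which is how the `dose_scale` field works.

The adult typical values (`adult_params()`) are, in L/h, L, 1/h and h:
CL 629, CLM1 217, V2 517, Q 89.9, V3 777, ka 5.22, ALAG1 0.156, Fm 0.7
(fixed), CLM 17, V4 189, Q1 60, V5 448. Units are mg, L and h internally, so
concentrations come out in mg/L; `convert_conc()` moves to assay-scale
ng/mL (x1000) for display only.

An important consequence used throughout the tests: for any linear model,
AUC extrapolated to infinity obeys exact mass balances,

    AUC_spir = Dose * f / CLtot
    AUC_can  = Dose * f * Fm * CLM1 / (CLtot * CLM),

which gives closed-form oracles for the solver and the NCA code with no
circularity.

### Solver

The five-state system (depot, SPIR central/peripheral, CAN
central/peripheral) is linear and time-invariant, so `solve_profile()`
diagonalizes the rate matrix once and writes the solution as a superposition
of dose impulses — exact up to the eigendecomposition, and fast enough for
Monte Carlo work (the rate matrix is block-triangular with real, negative
eigenvalues for physiologic parameters). Whenever the decomposition is
unreliable (near-coincident rate constants, e.g. `ka` equal to a disposition
eigenvalue), the code falls back to `deSolve::lsoda` with tight tolerances
(rtol 1e-10, atol 1e-12); the two paths agree to ~1e-7 relative wherever
concentrations are above the integrator's noise floor, which is verified on
random parameter draws in the test suite. The absorption lag is an exact
time shift of each dose's depot input (NONMEM `ALAG` semantics), not a
transit-compartment approximation.

## Population variability

Between-subject variability is log-normal per parameter,
`P_i = P_typ * exp(eta)`, with variances (NONMEM `OMEGA`, log scale):
ka 0.9, cl 0.166, v2 0.118, q 0.08, clm1 0.18, clm 0.08, v4 0.03, q1 0.07,
v5 0.09, and covariance 0.112 between the `cl` and `v2` effects (drawn
jointly via the Cholesky factor of the 2x2 block; an exactly singular block
is jittered by 1e-12 with a warning). `alag1`, `fm` and `v3` carry no random
effect. Residual error is proportional per analyte,
`obs = pred * (1 + eps)`, with variances 0.08 (SPIR) and 0.017 (CAN); draws
that would be negative are floored at zero and counted in an attribute
rather than redrawn, so the flooring is visible and testable. No truncation
is applied to the sampled `eta` — nothing in the adult analysis suggests
any. Both levels of variability are carried unchanged from adults to
children.

## Allometric bridging

Pediatric typical values use fixed-exponent allometry referenced to 70 kg:
exponent 0.75 for all five clearances, 1 for the four volumes, 0 for `ka`,
`alag1` and `fm`. The package ships the eight median weights for the
reference ages (2, 6, 12, 17 years by sex) recovered from the published
pediatric central-volume column as `70 * V2_ped / 517` — this reproduces the
full pediatric parameter grid to better than 0.1% without any growth-chart
download, and makes the grid self-validating through the identity
`cl_ped/cl_adult = (v2_ped/v2_adult)^0.75`. Two quirks are reproduced as
printed rather than corrected: the 17-year female implied weight (64.2 kg)
exceeds the male one (54.7 kg), and the grid prints a pediatric lag of
0.160 h although the lag is not weight-scaled; the package keeps the adult
0.156 h and treats 0.160 as rounding. Ages are accepted in [2, 17]; 17 is
the reference age for the upper edge of the oldest group.

## Clinical scenarios

`scenario_spec()` materializes multiplicative modifiers:

* cirrhosis — `cl` x (1 - 0.8444), `clm1` x (1 - 0.3776),
  `clm` x (1 - 0.7155); absorption untouched. These reductions reproduce the
  much longer half-lives reported in cirrhotic adults: the SPIR disposition
  half-life moves from 7.8 to 11.8 h and CAN from 30 to 95 h.
* food (high-fat, high-calorie meal) — `ka` x (1 - 0.935) (93.5% is used as
  the canonical figure over the narrative "nearly 94%"), `fm` x (1 - 0.60)
  (0.7 to 0.28) and `dose_scale` x 2; clearances untouched.

The two flags compose; applying a scenario to already-modified parameters is
refused so modifiers can never compound silently. With the slowed `ka`
(0.339/h) absorption becomes rate-limiting and flip-flop kinetics emerge on
their own; no explicit swap of the elimination constant is performed, and no
alternative "literal swap" mode is shipped. Note one subtlety the tests
verify explicitly: the `fm` drop raises `CLtot` to
`629 * 0.72 + 217 * 0.28 = 513.6` L/h, so the fed/fasted SPIR AUC ratio is
`2 * 340.6 / 513.6 = 1.33`, not the bare bioavailability doubling.

## Dose selection

`dose_sweep()` follows the simulation design of the original analysis:
N = 200 virtual subjects per reference age (100 per sex) at each dose in
0.25–2 mg/kg, with adult variability carried over; exposures are summarized
as mean, SD and the 5th–95th percentile band of AUC extrapolated to
infinity, and each pediatric age cell is compared against simulated adult
reference cohorts (200 subjects at 70 kg) given 25 and 100 mg. The
similarity rule is the one drawn in the original forest plots: the pediatric
mean must fall inside the adult 5th–95th prediction interval (no numeric
equivalence bound exists to be stricter against). AUC to infinity is the
headline metric; `auc_last` is also reported. Exposure metrics are computed
on model-predicted (residual-error-free) profiles by noncompartmental
analysis on a grid spanning 0–240 h.

The NCA itself uses linear-up/log-down trapezoids; the terminal slope comes
from a log-linear regression over the candidate terminal window (at least 3
positive points after and excluding Cmax, windows capped at 30 points)
maximizing adjusted R²; when no acceptable window exists the extrapolated
AUC is flagged missing rather than guessed.

## Sparse sampling design and its evaluation

The proposed study takes three age groups (12–<17, 6–<12, 2–<6 years, 6
subjects each), randomized 1:1 within group to one of two interleaved day-1
window sets (four windows in the oldest group, three otherwise), plus one
sample in each of 46–50 h and 166–170 h — 6 samples per subject in group 1,
5 in groups 2–3, both analytes assayed at every draw. Sampling times are
uniform within windows (the design only says "at random"); the two
subgroups jointly cover 0.08–8 h with no gap.

Design quality is quantified twice:

* **Expected precision** (`expected_rse_fim()`): the first-order population
  Fisher information for the fixed effects, on the log-parameter scale. Per
  subject `V = G Omega G' + diag(eps)` with `G` the eta-sensitivities of
  log-concentration, and the information is `J' V^-1 J` summed over
  subjects; `%RSE = 100 * sqrt(diag(FIM^-1))`, which on the log scale is
  directly the relative SE (reparameterization-invariant, matching the
  NONMEM convention of RSE relative to the estimate).
* **Empirical precision** (`evaluate_design()`): simulate the study, refit,
  repeat; `%RSE = 100 * sd(estimate)/truth` across replicates.

Six structural parameters are estimated (`cl, clm1, v2, clm, v4, ka`) with
the rest fixed at truth: 18 subjects contributing at most 6 samples each
cannot inform 12 fixed effects plus 10 variance components, and the choice
is configurable. The estimator (`fit_pooled()`) is deliberately *not* a full
nonlinear mixed-effects fit: it is pooled nonlinear least squares on log
concentrations with all subjects tied to adult-referenced parameters through
the fixed allometric exponents, plus two first-order corrections frozen at
the initial estimate:

1. **Correlated GLS whitening.** All observations of a subject share one
   `eta` draw, so their log-scale covariance `V = G Omega G' + diag(eps)`
   has strong off-diagonal structure. Residuals are whitened with the
   Cholesky factor of `V` (a 1e-8 ridge keeps the factorization defined when
   the residual variance is zero). Diagonal-only weighting was tried first
   and left the estimator far from the information bound.
2. **Second-order mean correction.** With log-normal BSV the marginal mean
   of log-concentration is `log f(0) + tr(Omega H)/2` (H the eta-Hessian),
   and the proportional residual contributes `-eps/2`. Without this
   correction the pooled estimates of `v2` and `ka` are biased upward by
   tens of percent at `omega²_ka = 0.9`; with it, median bias across 100
   replicates is below ~5% for `cl`, `clm1`, `v2` and `clm`.

Optimization runs in log-parameter space with Levenberg–Marquardt
(`minpack.lm::nls.lm`), restarting up to 3 times from initials perturbed
with 20% CV on non-convergence. Asymptotic %RSE comes from the whitened
Jacobian. Observations at model-predicted concentrations below 1e-12 mg/L
(for example a draw inside the 5–30 min window that lands before the
0.156 h absorption lag) carry no information and are excluded; zero or
negative observed values are likewise dropped from the log-scale fit.

Under the default design the FO information path predicts a maximum %RSE of
about 30% (driven by `ka`, the parameter with the largest BSV), below the
35% benchmark for all estimated parameters, and the empirical path agrees
within a factor of about 1.5 per parameter. The FO linearization is known to
be optimistic for very large random-effect variances, which is exactly the
regime of `ka` here — the 2-fold agreement band in the acceptance checks
reflects that, and a full Laplace/FOCE estimator would be the natural next
step if tighter agreement were needed.

## Synthetic data

No adult concentration data are public, so `generate_adult_study()` creates
a statistical stand-in for the phase-I studies: 92 subjects (14 at 25 mg, 78
at 100 mg, fasted), body weights normal with mean 64.1 and SD 6.4 kg
truncated above 40 kg (the adult model carries no weight covariate; weights
are realistic covariate dressing only), log-normal BSV, proportional
residual error, and a rich 16-point grid from 0.25 to 120 h chosen to span
absorption through the CAN terminal phase — the actual phase-I sampling
times are not published, so this grid is a declared assumption.
`generate_fed_arm()` produces the 23-subject fed/fasted crossover with
within-subject random effects shared across periods, and `truth_bundle()`
exposes the generating parameters and latent effects for recovery
experiments. The generators do not simulate assay censoring (LLOQ), tablet
comparator arms, or the one excluded protocol-deviation subject (the 92
count already reflects the exclusion).

What passing tests on these data do and do not show: parameter recovery
within 15% on a synthetic 92-subject study demonstrates that the estimation
machinery is consistent with its own generating model at a realistic design;
it cannot validate the published adult estimates themselves, which came from
proprietary data and a different (FOCEI mixed-effects) estimator.

## Numerical choices and problem sizes

* Eigen solver with lsoda fallback as above; solver agreement is tested at
  20 random parameter draws.
* NCA: log-down rule applied only on strictly decreasing positive segments;
  AUC refinement consistency holds for points on the integrator's own
  interpolant.
* FIM/fitting derivatives: central differences on log-parameters (step 1e-4;
  1e-3 for the Hessian trace), adequate for an exact underlying solver.
* Dose amounts are kept at full precision (no syringe-graduation rounding).
* Default run sizes: dose selection 200 subjects/age at two doses plus two
  200-subject adult reference arms; design evaluation 100
  simulation/re-estimation replicates of the 18-subject study; these run in
  roughly a minute each on one core and are the sizes used by the
  reproduction script.
* Determinism: every stochastic function draws from R's global RNG, so
  `set.seed()` before a call reproduces cohorts, datasets and sweeps
  bitwise.

## Known limitations

* Everything is linear: no saturable metabolism, no IV route, no TMS or
  further metabolites, no protein-binding model.
* Extrapolation stops at 2 years; no maturation functions below that age.
* The cirrhosis and food modifiers are point estimates applied to typical
  values; their own uncertainty is not propagated, and cirrhotic BSV is
  kept at the healthy-adult values.
* The pooled estimator is a first-order approximation; its %RSE and bias
  claims are statements about this estimator, not about a NONMEM FOCEI fit
  of the same design.
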