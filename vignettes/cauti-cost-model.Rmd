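---
title: "Modelling hospital CAUTI costs and intervention savings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hospital CAUTI costs and intervention savings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cauticost)
```

## The estimation problem

Catheter-associated urinary tract infection (CAUTI) imposes direct costs
that US hospitals have had to absorb since Medicare stopped reimbursing them.
`cauticost` answers two questions for a single hospital: *what does CAUTI
cost us now*, and *what would we save if we placed fewer urinary catheters,
or removed them sooner?* The package deliberately needs only two
hospital-specific inputs — annual admissions `N` and the proportion
catheterized `p` — and fills everything else with literature-based defaults
that the user may override.

## The trajectory model

After catheter placement we track four events: bacteriuria, symptomatic UTI
(SUTI), bloodstream infection (BSI), and catheter removal. Assuming
bacteriuria precedes any symptomatic infection, each patient follows one of
five trajectories: (1) no infection, (2) bacteriuria only, (3) bacteriuria +
SUTI, (4) bacteriuria + BSI, (5) bacteriuria + SUTI + BSI. Two conservative
simplifications make the costing tractable:

* asymptomatic bacteriuria is costless (trajectories 1–2 cost $0), and
* a patient with both SUTI and BSI is costed at the BSI cost alone.

Because the joint SUTI/BSI risk is not identified in the literature, SUTI is
further assumed to precede BSI, so the SUTI-but-no-BSI probability among the
bacteriuric is `q_S − q_B` (this is also why `risk_params()` rejects
`q_B > q_S` rather than clamping: the expected SUTI-only count would go
negative). Expected cost is then the multilinear map

$$E[\text{cost}] = N\,p\,R\big[(q_S - q_B)\,c_S + q_B\,c_B\big].$$

## Parameters, units, defaults

| Parameter | Meaning | Default (SE) |
|---|---|---|
| `R` | bacteriuria risk among catheterized | 0.26 (0.0153) |
| `q_S` | SUTI risk among bacteriuric | 0.24 (0.0408) |
| `q_B` | BSI risk among bacteriuric | 0.036 (0.0010) |
| `c_S` | per-patient SUTI cost, USD | 911 (911) |
| `c_B` | per-patient BSI cost, USD | 3824 (3824) |
| `r` | per-day bacteriuria risk | 0.05 (fixed) |
| `d` | mean catheterization, days | 6.68 (fixed) |

The defaults come from meta-analytic risk estimates and a microcosting study
with inflation-adjusted dollars. Proportions live on the `[0, 1]` scale and
percentage inputs are converted exactly once, at the input boundary. The
per-day risk and mean duration carry no standard errors; they feed only the
consistency diagnostic (`hazard_consistency_check()`, which warns when the
implied overall risk `r/(r + 1/d)` strays more than 10% from `R`; at the
defaults it implies 25.0% against the stated 26%) and the microsimulator.
Note the cost SEs equal their point estimates — a coefficient of variation of
1 — which dominates the width of every interval the package reports.

## Interventions and the duration closed form

An intervention is a pair of fractional reductions: `f_p` on placement and
`f_d` on mean duration. Placement scales `p` directly. Duration acts through
the race between bacteriuria onset and catheter removal: with constant
per-day hazards $\lambda_b$ (bacteriuria) and $\lambda_r$ (removal),
$R = \lambda_b/(\lambda_b + \lambda_r)$, so scaling mean duration by
$(1 - f_d)$ multiplies the odds $R/(1-R)$ by $(1-f_d)$, giving

$$R' = \frac{(1-f_d)R}{1 - f_d R}.$$

This continuous-time form was a genuine design choice: a discrete-time
per-day Bernoulli alternative ($R' = 1-(1-R)^{1-f_d}$) disagrees with the
continuous form by about 3% at a 40% duration reduction, and only the
continuous form is consistent with the exponential-duration microsimulator
the package uses as its oracle, so the continuous form is implemented
throughout. `R'` is monotone nonincreasing in `f_d`, equals `R` at `f_d = 0`,
and vanishes at `f_d = 1`; the conditional risks `q_S`, `q_B` and the
per-patient costs are held fixed across intervention. Savings are current
minus post-intervention cost and are therefore nonnegative and monotone in
both reductions.

## Uncertainty propagation

The five uncertain parameters `(R, q_S, q_B, c_S, c_B)` are treated as
mutually independent, since the literature provides marginal standard errors
and no covariances. For any scalar quantity `T` (current cost, projected
cost, savings) the delta method gives
$\mathrm{Var}(T) \approx \sum_i (\partial T/\partial \theta_i)^2\,SE_i^2$.
Partials are central differences with relative step `1e-6` (absolute floor
`1e-9`), which for this multilinear objective agrees with the analytic
gradient to better than `1e-6` relative — the test suite asserts exactly
that. Savings are differentiated as a *single* pre-minus-post map, so the
shared dependence of both cost terms on `R` flows through one partial and is
not double-counted.

Confidence intervals are formed on the log scale,
$\text{point}\cdot\exp(\pm z\,SE/\text{point})$ with the exact normal
quantile (1.959964 for 95%). The choice is forced by the estimator's
structure: with cost CVs of 1 the sampling distribution is strongly
right-skewed and a symmetric normal interval would cross zero. The log-scale
interval is multiplicatively symmetric, always positive, and collapses to
the symmetric normal interval as CVs shrink (also asserted in the tests). A
zero point estimate (e.g. savings under the null intervention) has no
meaningful multiplicative interval; the package returns a degenerate `(0, 0)`
interval rather than erroring.

`monte_carlo_propagation()` is a verification oracle, not the estimator: it
draws parameters from domain-respecting distributions — gamma for costs
(moment-matched, strictly positive support, which at CV = 1 is an
exponential), logit-normal for the three proportions with `(mu, sigma)`
matched numerically to the mean and SE — and summarizes the empirical draws.
Draws where `q_B` exceeds `q_S` are clipped to `q_S` and the clipped fraction
is reported. In the small-CV regime (all SEs scaled by 0.05) the empirical SD
matches the delta SE within 5% at 10^5 draws; at the default CV = 1 inputs
the two are *not* expected to agree closely — the delta method is a
first-order approximation and the reported intervals should be read as such.

## The microsimulator: what it emulates and what it does not

`simulate_cohort()` generates patients under exactly the model's assumed
structure: Bernoulli catheterization at `p(1-f_p)`; exponential duration
with mean `d(1-f_d)`; bacteriuria when an exponential time with hazard
`lambda_b = R/(d(1-R))` precedes removal; SUTI as Bernoulli(`q_S`) given
bacteriuria; BSI as Bernoulli(`q_B/q_S`) given SUTI, so the marginal BSI
risk among the bacteriuric is `q_B` while BSI-without-SUTI (trajectory 4) is
never generated. The hazard is back-derived from `R` and `d` rather than
from the rounded 5%/day input so that the simulator targets the closed form
it is meant to validate. Nesting BSI inside SUTI is one consistent
construction of the unidentified joint mechanism, not the only one.

Agreement between simulator and closed forms (cohort mean cost within 4
Monte-Carlo SEs at 2×10^5 patients; bacteriuria fractions within 3 binomial
SEs at 10^6 competing-exponential draws across duration reductions 0–0.75)
therefore validates the *implementation*, not the model: real hospitals have
non-exponential catheter durations, time-varying hazards, recatheterization,
and between-hospital quality variation, none of which are modelled. The
simulator also ignores length of stay and patient-to-patient transmission.

## Numerical and interface choices

* Expected counts are real-valued expectations; rounding to whole patients
  or dollars happens only in display formatting.
* Grid defaults span 0–50% reductions in 10% steps on both axes, covering
  all intervention scenarios the package's acceptance checks exercise; the
  grid's cell-level relative SE at the default inputs sits in a narrow band
  (~0.72) because the cost CVs dominate every cell.
* Config files are flat YAML or JSON key/value documents; unknown keys warn
  and are ignored, missing risk/cost keys fall back to the packaged
  defaults, and `admissions`/`prop_catheterized` are required.
* The CLI is a thin shell over exported functions (exit codes: 0 success,
  2 validation error, 1 unexpected failure); every number it prints is
  reproducible by direct function calls with the same config.
* Test problem sizes (2×10^5-patient cohorts, 10^6 competing-exponential
  draws, 10^5 Monte-Carlo parameter draws) were chosen so the whole suite
  completes in a few seconds while leaving the stochastic acceptance bands
  (3–4 SEs) far wider than the observed deviations.

## Known limitations

The estimator inherits the literature defaults' vintage: the per-patient
costs are rounded, inflation-adjusted dollars, which bounds reproduction of
any published figure derived from them at roughly the 0.1% level and is why
the package's own checks use a 1% relative tolerance. Uncertainty excludes
`r` and `d` (no published SEs), assumes independence, and is first-order
only; intervals at CV = 1 are approximations, not exact coverage statements.
Intervention and opportunity costs are out of scope — reported savings are
gross, not net of what the intervention itself costs.
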