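---
title: "Monte Carlo target attainment for beta-lactams during CRRT: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo target attainment for beta-lactams during CRRT: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crrtpta)
```

## The question the package answers

Critically ill patients with acute kidney injury on continuous renal
replacement therapy (CRRT) receive beta-lactam and carbapenem antibiotics
under large pharmacokinetic uncertainty: sepsis and fluid resuscitation
inflate the volume of distribution, protein binding is erratic, and the
extracorporeal circuit removes drug in proportion to the delivered effluent
flow. For time-dependent antibiotics the pharmacodynamic (PD) driver is the
time the *free* (unbound) concentration spends at or above the pathogen's
minimum inhibitory concentration (MIC). `crrtpta` simulates large virtual
populations of such patients, computes free concentration--time profiles
over the first 72 h of a dosing regimen, and reports the probability of
target attainment (PTA) -- the fraction of patients meeting a PD target --
overall and within body-weight quartiles, so that the influence of patient
size on dosing adequacy can be read directly off the tables.

## Virtual patient model

Each patient is a draw of seven quantities: body weight (kg),
weight-normalized volume of distribution $V_d$ (L/kg), free fraction $f_u$,
nonrenal clearance $CL_{NR}$ (mL/min), sieving coefficient $SC$, prescribed
effluent rate $Q_{eff}$ (mL/kg/h) and the delivered fraction of CRRT.
All are sampled from log-normal distributions parameterized by their
*arithmetic* mean and SD (moment matching: $\sigma^2 = \ln(1 + sd^2/m^2)$,
$\mu = \ln m - \sigma^2/2$) and constrained to preset limits by rejection
sampling. Rejection -- rather than clipping -- preserves the distributional
shape inside the bounds; the realized moments of heavily truncated
parameters (e.g. free fractions bounded by 1) are therefore those of the
conditional distribution, which is intended behaviour and is tested against
a numerical-integration oracle rather than against the nominal moments.
Body weight is truncated below at 40 kg with no upper limit.

Two parameters are correlated with weight. The packaged scenario stores a
squared correlation $r^2$ for weight--$V_d$ and weight--$CL_{NR}$ per drug;
sampling induces a rank-based association targeting $r = +\sqrt{r^2}$ via a
Gaussian-copula score (normal scores of the weight ranks mixed with
independent noise), an Iman--Conover-style reordering that leaves the
marginals exactly unchanged. The positive sign follows from the observed
quartile summaries (heavier patients have the larger $V_d$/kg); the two
correlations are induced independently (no $V_d$--$CL_{NR}$
cross-correlation is specified). Whether the source data's correlation was
a product-moment or a rank coefficient is not recoverable; the rank-based
reading is adopted, and the realized Pearson correlation lands within
$\pm 0.05$ of $\sqrt{r^2}$ for every drug (tested). A consequence worth
knowing: with the imipenem configuration ($r^2 = 0.17$) the lightest
quartile's mean $V_d$ comes out near 0.30 L/kg; a weaker reading of the
correlation (e.g. inducing at $\rho = r^2$) would flatten the quartile
gradient by roughly a third.

Derived per-patient quantities:

$$CL_{CRRT} = SC \cdot Q_{eff} \cdot weight \cdot delivered / 1000
\quad \text{(L/h)},$$
$$CL_{total} = 0.06 \, CL_{NR} + CL_{CRRT}, \qquad
k_e = CL_{total} / (V_d \cdot weight).$$

Residual native renal clearance is deliberately absent (anuric AKI is
assumed), as are inter-occasion variability and any covariate model beyond
the weight correlations. The replacement-fluid rate is stored in the
scenario but does not enter the clearance model; its role is not defined by
the source configuration and its intensive-arm entry duplicates the
delivered-fraction distribution, which looks like a transcription artifact.

## Pharmacokinetic engine

Concentrations follow a one-compartment, first-order model with repeated
zero-order infusions. The engine is analytic superposition, not an ODE
solver: a dose starting at $t_k$ with rate $R_0 = dose/T_{inf}$ contributes
$(R_0/CL)(1 - e^{-k_e (t - t_k)})$ during the infusion and decays
mono-exponentially afterwards. The $CL \to 0$ limit (possible because
several sampled quantities have lower bound 0) is handled analytically:
linear accumulation during infusion, a flat profile afterwards. An adaptive
ODE integration serves as the independent oracle in the tests (relative
error below $10^{-6}$ on randomized patients); the analytic path is used in
production because a full study run touches $10^4$ patients times 58
regimen rows.

Free concentration is the sampled free fraction times total concentration;
the sieving coefficient is sampled independently of the free fraction
(both are listed separately in the scenario), so no protein-binding theory
links the two.

## Pharmacodynamic metrics

Three target families are evaluated per drug, all on free concentration
over the first 72 h:

* `%fT >= 1xMIC` at the drug-class percent-of-time threshold (40% for
  carbapenems, 50% for piperacillin/tazobactam, 60% for cephalosporins);
* `%fT >= 4xMIC` at the same percent threshold;
* `100%fT >= MIC`: never below the MIC.

Time above a threshold is computed exactly: every inter-event segment of
the profile is monotone, so threshold crossings are solved in closed form
within segments, and grid density cannot bias the result (a brute-force
dense-grid oracle agrees to $10^{-4}$ in the tests). Comparisons use
$\geq$, so a profile sitting exactly at the threshold counts as above;
the boundary has measure zero except in the degenerate zero-clearance case,
where the convention matters and is pinned by tests.

The always-above target needs a convention, because concentration is
identically zero at $t = 0$: evaluated literally on $[0, 72]$ the target is
unattainable. The default window runs from the end of the first infusion to
72 h. An alternative reading -- all inter-dose troughs and the final
concentration at or above the MIC -- is available via
`always_above_mode = "troughs"`. The two differ only through the end of the
first infusion being checked, and in practice the binding constraint is the
first inter-dose trough (accumulation raises all later troughs), so the
choice is nearly immaterial; the window reading is the default. The `%fT`
targets are computed over the literal $[0, 72]$ including the initial ramp.

Dominance invariants are asserted per patient across full runs: time above
4xMIC never exceeds time above 1xMIC, and an always-above patient always
attains the `%fT >= 1xMIC` target (the sub-MIC ramp is at most the first
infusion, far below the loosest percent threshold).

## Aggregation and classification

Cohorts of $n = 10{,}000$ (any multiple of 4 is accepted) are stably sorted
by weight and split into four quartiles of exactly $n/4$; reported weight
ranges are the per-cohort min/max per quartile rounded to integer kg, so
ranges differ slightly between regimens when cohorts are resampled. With
equal quartile sizes the overall PTA is exactly the mean of the quartile
PTAs (tested). Cells are classified green (PTA $\geq 90\%$, the customary
optimality threshold for dosing simulations), orange ($60 \le$ PTA
$< 90\%$) and red ($< 60\%$); classification uses unrounded values, tables
print one decimal. `find_optimal_regimen()` returns the first candidate --
ordered by total daily dose, then dosing frequency -- whose PTA reaches
90% for the chosen target and group.

## Tunable parameters

| parameter | default | units | note |
|---|---|---|---|
| `infusion_duration` | 0.5 | h | standard intermittent infusion; the source configuration does not state one. The always-above target is the most sensitive to this choice (longer infusions lower peaks but barely move troughs); it is exposed both in the scenario file and as an argument. |
| `horizon` | 72 | h | PD evaluation window |
| `n` | 10000 | patients | 2500 per quartile; binomial SE $\le 0.5$ points overall, $\le 1$ point per quartile cell |
| `grid_step` | 0.05 | h | output grid of `conc_profile()` only; PD metrics are grid-free |
| `always_above_mode` | `post_first_infusion` | -- | see above |
| `resample_per_regimen` | `FALSE` | -- | one shared cohort per (drug, arm) reduces between-regimen Monte Carlo noise; set `TRUE` to model every regimen on a fresh cohort |

Seeds: `run_simulation()` derives one sub-seed per (drug, arm) from the
master seed with a stable hash (`derive_seed()`), so a subset run
reproduces the corresponding cells of a full run bit-for-bit.

## What the generator emulates, and what it does not

The sampler stands in for a critically ill CRRT trial population: weights
from a log-normal with mean 84 kg truncated at 40 kg, two CRRT intensity
arms (prescribed effluent 22 vs 35.8 mL/kg/h with under-delivery sampled
separately), and drug parameters whose dispersion reflects critically ill
-- not healthy-volunteer -- cohorts. It does not emulate: body composition
(no BMI; weight acts only through $V_d$ scaling and $CL_{CRRT}$),
within-patient variation over the 72 h (parameters are frozen per patient),
circuit downtime patterns (delivered fraction is one static multiplier),
MIC distributions (fixed breakpoints only), or combination PD
(piperacillin and tazobactam are simulated separately). Passing tests
therefore demonstrate correctness of the sampling, PK arithmetic and
aggregation under these assumptions -- not clinical validity of a dosing
recommendation, and no toxicity ceiling is modelled.

Published tables of this kind are also sensitive to conventions their
authors rarely report (infusion duration, the always-above window, how a
spreadsheet truncates distributions). The stochastic-reproduction checks in
`tests/testthat/test-acceptance.R` are honest about this: cells driven by
`%fT` metrics and by the fast-clearance carbapenems reproduce closely,
while several published-style always-above cells do not reproduce under any
convention this model supports; the acceptance suite leaves those
assertions failing rather than bending the model toward them, and
`scripts/acceptance.R` recomputes all reported quantities from scratch so
the gap is visible.

## Numerical and testing notes

* Truncated sampling rejects in batches sized by the analytic acceptance
  probability; an interval holding less than $10^{-6}$ of the mass is an
  error, and `sd = 0` short-circuits to the constant.
* Ties in the weight sort break by patient index (stable), pinned by test.
* Problem sizes in the test suite are the package's working defaults:
  $10^5$ draws for sampler moment checks, $10^4$ patients for PTA and
  correlation checks, 100 randomized patients for each oracle comparison.
* The scenario YAML round-trips losslessly (written with 12 significant
  digits); every packaged value is asserted digit-for-digit in the tests.
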