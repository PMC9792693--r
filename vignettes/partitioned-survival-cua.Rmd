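---
title: "Methods: a partitioned survival cost-utility model for first-line immunochemotherapy in metastatic NSCLC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a partitioned survival cost-utility model for first-line immunochemotherapy in metastatic NSCLC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(partsacea)
```

## The decision problem

`partsacea` evaluates whether adding the PD-L1 inhibitor sugemalimab to
platinum-based chemotherapy is cost-effective for first-line treatment of
metastatic non-small cell lung cancer from the Chinese health-system
perspective. Two strategies are compared: sugemalimab (1200 mg every three
weeks) plus a platinum doublet, versus placebo plus the same doublet, with
the doublet chosen by histology (carboplatin-paclitaxel for squamous,
carboplatin-pemetrexed for non-squamous disease), four induction cycles,
maintenance until progression or a 35-cycle cap, and a mix of docetaxel,
crossover sugemalimab and best supportive care after progression. Outcomes
are discounted cost (USD), life-years, QALYs and the incremental
cost-effectiveness ratio (ICER), judged against a willingness-to-pay
threshold of three times 2021 Chinese per-capita GDP (36,203.88 USD/QALY).

## Model structure

The model is a three-state partitioned survival analysis (PartSA):
progression-free (PFS), progressed disease (PD) and death. State occupancy
is read directly off two survival curves per arm rather than from
transition rates:

$$p_{PFS}(t) = \min\{S_{PFS}(t),\, S_{OS}(t)\}, \qquad
  p_{death}(t) = 1 - S_{OS}(t), \qquad
  p_{PD}(t) = S_{OS}(t) - p_{PFS}(t),$$

with the clamp handling extrapolated curves that cross. The cycle length
equals the 21-day administration cycle (0.69 months at 30.4375 days per
month); the base-case horizon is 10 years, by which time almost the entire
cohort has died, so no terminal value is added beyond it. The final cycle
is truncated so the cycle widths tile the horizon exactly.

Membership is evaluated at cycle starts by default. This left-endpoint
convention matches the published totals; it overstates occupancy time by
at most half a cycle relative to the continuous integral. With half-cycle
correction (`half_cycle_correction = TRUE`, midpoint evaluation) the
accrual agrees with a daily-step oracle to well within 0.5%, which the
test suite asserts; the gap between the two conventions is what the
engine's discretization can contribute to any reported total, and it is
small against the reproduction tolerances used here.

### Discounting

Costs and utilities are discounted at 5% per year. The default applies the
factor in discrete annual steps, $(1+r)^{-\lfloor t \rfloor}$, the
behaviour of the cycle-tree software in which models of this kind are
usually built; under it the deterministic base case tracks the published
per-arm totals noticeably more closely than continuous compounding
$(1+r)^{-t}$, which remains available via
`model_settings(discounting = "continuous")`. Life-years are discounted
like QALYs and costs.

## Survival inputs

Survival curves are `surv_dist` objects. The five standard families use
these parameterizations (time in months):

* log-logistic: $S(t) = 1/(1 + (t/\lambda)^\gamma)$ — the scale $\lambda$
  *is* the median. The published shape/scale pairs are read on this
  accelerated-failure-time scale because it reproduces the trial medians
  (sugemalimab PFS scale 9.35 months against a 9.0-month trial median).
* log-normal: $S(t) = 1 - \Phi((\ln t - \mu)/\sigma)$, with the published
  "shape/scale" pair read as $(\mu, \sigma)$ = (meanlog, sdlog); the
  implied placebo OS median $e^{2.8289} \approx 16.9$ months sits next to
  the trial's 17.7 months, which fixes the otherwise ambiguous labeling.
* exponential, Weibull (as `stats::pweibull`), and Gompertz with hazard
  $b\,e^{at}$; a negative Gompertz shape gives an improper distribution
  with plateau $e^{b/a}$ — allowed, since the horizon is finite, but
  flagged when printed.

Three flexible families support the extrapolation scenarios: a mixture
cure model $S(t) = \pi + (1-\pi)S_0(t)$, a non-mixture cure model
$S(t) = \pi^{1-S_0(t)}$ (both plateau at the cure fraction $\pi$, and
$\pi = 0$ recovers the base family exactly), and a Royston-Parmar natural
cubic spline for the log cumulative hazard in log time, on the
proportional-hazards scale.

### Fitting and model selection

`fit_parsurv()` maximizes the right-censored log-likelihood
$\sum_{events}\ln f(t_i) + \sum_{cens}\ln S(t_i)$ with BFGS on an
unconstrained scale (log for positive parameters, logit for the cure
fraction) from fixed moment-style starting values, so refitting the same
data reproduces the same estimates. The spline family is fitted through
`flexsurv::flexsurvspline` with one internal knot at the median log event
time and boundary knots at the extreme event times (configurable); its
survival function is evaluated by the package's own spline basis, which
the tests pin against `flexsurv` to machine precision. The hand-written
likelihood is itself cross-checked against `flexsurvreg` on censored
Weibull data. `select_best()` ranks converged fits by AIC
($2k - 2\ell$), breaking ties by BIC ($k\ln n - 2\ell$) and then by
parsimony. All-censored data and non-convergence are surfaced, never
silently accepted.

## The synthetic trial generator

No patient-level data from the source trial are available, so
`simulate_trial()` stands in for it. Defaults were chosen once to emulate
the trial's scale and maturity: 2:1 randomization with 320 and 160
patients, uniform accrual over 12 months, and a common administrative
cutoff 30 months after study start; per-arm PFS and OS marginals follow
the published best-fit curves. Progression and death times are coupled
comonotonically (a shared uniform drives both quantile functions, with
bounded redraws of the death time where the raw draw would precede
progression) and the PFS endpoint is the earlier of progression and
death, so PFS never exceeds OS patient-wise. Only the marginals matter to
the PartSA engine; the coupling merely keeps the joint data plausible.

`reconstruct_ipd()` closes the loop for published curves: a Guyot-style
inversion that, within each numbers-at-risk interval of a digitized curve,
spreads censoring uniformly, recovers event counts from the drops of the
Kaplan-Meier product, and picks the censored count that matches the next
published number at risk. Round-tripping a simulated cohort through
digitization (0.25-month grid, finer than one model cycle) and
reconstruction reproduces the original Kaplan-Meier curve to within 0.02
survival units in the tests.

What the generator deliberately does not emulate: informative dropout
(censoring is purely administrative), and any departure of true survival
from the published parametric curves. The second omission matters for the
cure-model scenarios. In the source evaluation the placebo arm's real OS
curve carried a late plateau — more than a quarter of placebo patients
crossed over to sugemalimab after progression — which a log-normal
understates and a cure model captures, narrowing the incremental QALY and
raising the ICER. Synthetic data drawn *from* the log-normal cannot
contain that plateau, so cure models fitted to it assign the larger cure
fraction to the sugemalimab arm (whose Kaplan-Meier curve sits higher at
cutoff) and move the ICER the opposite way. Passing tests on synthetic
data therefore validate the machinery, not real-data extrapolation
behaviour; the corresponding directional check in the acceptance tests
documents this divergence rather than hiding it.

## Valuation conventions

* **Whole-vial pricing.** Doses are rounded up to whole vials with no
  sharing: 1200 mg of sugemalimab in 600 mg vials costs exactly two vials
  (3688.52 USD per cycle), consistent with the published per-cycle
  acquisition cost.
* **Dosing.** Body surface area 1.72 m², GFR 70 ml/min; carboplatin by
  the Calvert formula AUC×(GFR+25) = 475 mg; pemetrexed 500 mg/m²,
  paclitaxel 175 mg/m²; docetaxel after progression at the guideline
  75 mg/m² every three weeks (the source names docetaxel without a dose).
* **Histology mix.** The squamous fraction weighting
  paclitaxel vs pemetrexed is not published; the default 0.4 approximates
  the trial composition and is swept in the one-way analysis. It is the
  main unfixed economic input.
* **Treatment-phase costs** attach to PFS occupancy: expected drug cost
  at cycle $k$ is $p_{PFS}(k)$ times the cycle's regimen cost, induction
  through cycle 4, maintenance through the 35-cycle cap, plus
  hospital-management and follow-up fees per on-treatment cycle.
* **Post-progression costs** apply the arm's subsequent-treatment mix
  (docetaxel / crossover sugemalimab / best supportive care, each plus
  follow-up) to every cycle of PD occupancy, uncapped. Best supportive
  care is priced per cycle, and the published comparator-arm total is
  consistent with the uncapped convention and not with stopping the
  crossover component at the 35-cycle mark; a cap remains available via
  `pd_crossover_cap_cycles`.
* **Serious adverse events** (grade ≥ 3, incidence ≥ 10%) enter once, in
  the first cycle: the arm's aggregate management cost, and a QALY loss
  $\sum_i p_i\,|d_i|$ carried for one cycle length. Utilities are 0.804
  (PFS) and 0.321 (PD).

Arm totals decompose exactly into labeled components (immunotherapy —
first-line plus crossover — chemotherapy, hospital, follow-up, subsequent
therapy, SAE), which is what lets a sugemalimab price factor scale
exactly and only the immunotherapy component.

## Sensitivity and scenario analysis

The one-way analysis moves each parameter alone to its bounds: the
sugemalimab price from 50% of list to list price, the discount rate over
0–8%, utilities, disutilities and adverse-event probabilities over their
published ranges, everything else ±20%; entries are ranked by tornado
width on the ICER scale.

The probabilistic analysis runs 1,000 second-order Monte Carlo draws:
gamma for costs and beta for probabilities, utilities and disutility
magnitudes, moment-matched to mean = base and sd = (high−low)/3.92 (the
range read as a 95% interval; the published table gives ranges, not
standard errors). A beta standard deviation infeasible for its mean is
clipped with a warning. Independent beta draws of the two state utilities
cross their ordering in roughly 2 in 10,000 draws; the PD utility of an
offending draw is resampled so every draw respects
$u_{PD} \le u_{PFS}$. Survival-curve parameters are held fixed — the
published input table lists no sampling distribution for them — which
understates decision uncertainty and is the analysis's main structural
limitation. The acceptability curve evaluates net monetary benefit
$w\,\Delta QALY - \Delta cost$ over a 0–400,000 USD grid in 2,000-USD
steps.

Scenarios rerun the deterministic model with the sugemalimab price at 30%
and 10% of list (scaling first-line and crossover use alike), horizons of
5 and 20 years, and alternative OS extrapolations (mixture cure,
non-mixture cure, Royston-Parmar) fitted to synthetic trial data.

## Problem sizes and numerical choices

Parameter-recovery tests use 2,000 observations with 30% administrative
censoring (both log-logistic parameters back within 10%) and 5,000
uncensored exponential draws (rate within 5%); the empirical-convergence
check compares 10,000 simulated survival times against the generating
curve at a Kolmogorov-Smirnov threshold of 0.03; the mean-preservation
check of the probabilistic machinery uses 10,000 draws. Restricted means
are computed by adaptive quadrature (`stats::integrate`, relative
tolerance 1e-9) and checked against a million-point trapezoid. Occupancy
conservation holds to 1e-12 per cycle by construction and is asserted at
that tolerance.

## Known limitations

PFS and OS enter as independent marginal curves, as PartSA requires —
there is no within-patient transition structure, so the PD sojourn is an
arithmetic remainder. Curve uncertainty is excluded from the
probabilistic analysis. Utilities come from a general multi-regional
population rather than trial patients. The synthetic generator reproduces
the published parametric world, not the real trial's crossover-shaped
tails; conclusions about flexible-model extrapolation on real data should
not be drawn from it.
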