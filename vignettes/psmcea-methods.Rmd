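---
title: "Methods: partitioned survival cost-effectiveness modelling in psmcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioned survival cost-effectiveness modelling in psmcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

## The decision problem

`psmcea` implements a trial-based cost-effectiveness pipeline for first-line
systemic therapy in unresectable hepatocellular carcinoma (uHCC), comparing
dual immunotherapy (nivolumab 1 mg/kg + ipilimumab 3 mg/kg every 3 weeks for
up to four doses, then nivolumab 480 mg every 4 weeks) against
investigator's-choice targeted therapy (lenvatinib 8/12 mg daily or
sorafenib 400 mg twice daily), from the US and Chinese payer perspectives.
The pipeline runs from published-figure inputs to incremental
cost-effectiveness ratios (ICERs):

1. validate digitized Kaplan–Meier (KM) coordinates;
2. reconstruct pseudo individual-patient data (IPD) constrained by
   number-at-risk tables;
3. fit five parametric survival families by censored maximum likelihood and
   average them with Akaike weights;
4. read four-state occupancies off the extrapolated curves (partitioned
   survival model, PSM);
5. accrue discounted costs and quality-adjusted life-years (QALYs);
6. quantify uncertainty (tornado, two-way price grid, probabilistic
   sensitivity analysis, price thresholds, scenarios).

Because the underlying trial's figures and unit-cost supplement are not
redistributable, a synthetic-trial generator with known ground truth stands
in for them; every stage is tested against that truth.

## Synthetic trials

`default_scenario()` emulates the structure of the motivating phase III
trial: 335 vs 333 subjects (intention-to-treat) or 98 vs 110
(China subgroup). Event times are generated sequentially:
progression-free survival (PFS) is exponential with median 9.1 / 9.2 months
per arm, and overall survival (OS) is PFS plus an exponential
post-progression sojourn whose medians (10.4979 and 7.8393 months) were
solved so the OS marginals have medians 23.7 and 20.6 months (descriptive
hazard ratio 0.79). The sequential construction guarantees
`PFS <= OS` per subject and `S_PFS(t) <= S_OS(t)` marginally — the ordering
a strictly sequential disease process implies. An independent-draw mode
(`correlate = FALSE`) draws OS from a named family directly and caps PFS at
OS.

Censoring is administrative: entry uniform over a 12-month accrual window,
cutoff 41.2 months after first enrolment, so potential follow-up is uniform
on [29.2, 41.2] with median 35.2 months, the published median follow-up.
The true censoring pattern of the trial is unpublished; this one-time
choice is the package's own.

What the generator does **not** emulate: non-proportional or cure-fraction
hazards, dependent (informative) censoring, response endpoints, and
individual cost heterogeneity. Passing tests therefore certify the
pipeline's arithmetic and statistical machinery on well-behaved inputs, not
the clinical validity of any particular extrapolation of real curves.

A practical note on power: with these effect sizes, single trial-sized
realizations vary visibly — realized OS medians at n≈335/arm scatter by
roughly ±2 months, and occasional seeds show almost no arm separation.
Analysis drivers report the realization they got; the test-suite
assertions use properties robust to this noise.

## Curve validation and pseudo-IPD reconstruction

Digitized coordinates carry small monotonicity violations.
`validate_curve()` clips upward steps of at most `tolerance` (default 0.01
survival units) to the running minimum, inserts a missing (0, 1) origin,
and rejects larger violations naming the offending point.

`reconstruct_ipd()` follows the standard iterative KM-inversion scheme:
within each number-at-risk interval it guesses the censoring count, spreads
those censorings uniformly over the interval, walks the curve coordinates
allocating integer event counts (`round(n_k (1 - S_k / KM_k))`, conditional
on the running product-limit estimate), and adjusts the censoring guess
until the implied risk set at the next grid time matches the table. Two
conventions matter and are deliberate:

* **Censorings leave the risk set before the next event coordinate.**
  Applying within-gap censorings before the coordinate's event allocation
  (ties resolve events-first) keeps the late risk sets honest; in stress
  tests this halved the worst-case tail error relative to applying them
  after.
* **Coordinate-wise conditional rounding** is used rather than a
  largest-remainder allocation per interval: rounding each event count
  against the running estimate self-corrects drift and reproduced the
  input curves more faithfully in round-trip tests.

Beyond the last risk-table entry the previous interval's censoring rate is
carried forward, unless a reported total event count is supplied
(`total_events`), in which case the tail censoring is chosen to match it
where feasible. Subjects still at risk at the last coordinate are censored
there. Infeasible combinations (curve drops the risk table cannot support)
raise an error with per-interval diagnostics; the achieved risk set per
grid time and the sup-norm of the round-trip product-limit estimate are
attached to every result.

On synthetic trials with 300 subjects/arm and 20–35% administrative
censoring the round-trip sup-norm error is typically 0.002–0.01. The error
is dominated by quantization at the curve tail: a reconstruction with
`n` subjects at risk cannot represent survival drops finer than `S/n`, so
configurations whose curves end high (S ≈ 0.3) with very sparse tails can
exceed 0.02 no matter the allocation rule.

## Parametric fitting and model averaging

Five families are fitted to the reconstructed IPD by right-censored maximum
likelihood, in the conventional health-technology-assessment
parameterizations (`survival_function()`): exponential
`exp(-rate t)`, Weibull `exp(-(t/scale)^shape)`, Gompertz
`exp(-(rate/shape)(e^{shape t}-1))`, log-normal
`1 - Phi((log t - meanlog)/sdlog)`, log-logistic `1/(1+(t/scale)^shape)`.
The exponential rate is the closed form `events / total follow-up` —
computed exactly, never via an optimizer. The two-parameter families use
Nelder–Mead on log-transformed positive parameters (Gompertz shape stays on
the natural scale and may go negative during fitting, the defective
decreasing-hazard form), started from accelerated-failure-time fits
(`survival::survreg`) plus deterministic jittered restarts, with a 1e-8
convergence tolerance on the log-likelihood. Tests cross-check the
resulting likelihoods and estimates against `flexsurv::flexsurvreg`.

Model averaging uses Akaike weights,
`w_i = exp(-(AIC_i - min AIC)/2)` normalized to sum to one; BIC is reported
in fit tables but does not enter the weights. The averaged survivor is the
weighted mean of the component survivor functions **on the survival
scale** — averaging predictions, not parameters or hazards — and is
evaluated on a monthly grid to 240 cycles (20 years) regardless of
follow-up. Whether averaging should instead act on the log-survival scale
is not determined by the source method; the survival scale keeps the
average a proper mixture (bounded by the component survivors), which is
what the bounding tests assert. PFS and OS ensembles are fitted
independently, with no joint constraint; crossings are handled in the PSM.

Goodness of fit is reported as the sup-norm and mean absolute deviation of
the averaged survivor against the digitized curve, alongside the per-family
AIC/BIC/weight table. Small-subgroup fits (n ≈ 100) routinely show tail
deviations of 0.1–0.2 against a plateaued KM curve; that is the familiar
extrapolation-versus-plateau disagreement, visible in the report rather
than hidden.

## The four-state partitioned survival model

States: PFS (first-line therapy), PFS2 (between first and second
progression, on second-line therapy), PD (after second progression), death
(absorbing). Monthly cycles, default horizon 240. Occupancies come off the
curves:

* `PFS(t) = min(S_PFS(t), S_OS(t))` — independently extrapolated ensembles
  can cross; the min() cap is the standard PSM repair and the affected
  cycles are flagged on the trace;
* `Death(t) = 1 - S_OS(t)`;
* the alive-but-progressed remainder `S_OS - PFS` is split between PFS2 and
  PD by an exponential-sojourn convolution: mass entering PFS2 at cycle `s`
  remains there at cycle `t` with probability
  `exp(-lambda2 (t - s + 1))` (one exit opportunity per completed cycle),
  truncated so PFS2 never exceeds the remainder, PD taking the rest.

The source model never states how PFS2 occupancy was operationalized; the
convolution with a configurable per-month exit hazard `pfs2_exit_rate`
(default `log(2)/6`, a 6-month median PFS2 sojourn typical of second-line
uHCC therapy) makes the assumption explicit and swappable — `0` keeps all
progressed mass in PFS2, `Inf` sends it straight to PD, and a
user-supplied second partition curve can replace the fitted PFS source in
scenarios. The exponent `t - s + 1` (not `t - s`) makes the instant-exit
limit exact.

Discounting is end-of-cycle on annual rates, `(1+r)^(-t/12)`; a half-cycle
(trapezoid) correction is available but off by default, matching per-cycle
accrual conventions of common decision-tree software. Occupancy
conservation (sum to 1 within 1e-9), death monotonicity and the
constant-hazard closed form are asserted in tests every cycle.

## Costs and QALYs

Cost categories: first-line drug acquisition and infusion administration
(weighted by PFS occupancy — treatment to progression), subsequent-line
therapy (PFS2 occupancy, priced as a weighted mean over regimen
proportions with the remainder at the best-supportive-care rate), best
supportive care (PD), follow-up (all alive states), adverse-event
management (once, in cycle 1: incidence × unit cost for grade ≥3 events
with between-arm differences), and a one-time end-of-life cost on incident
deaths. A month is 365.25/12 days for daily-dosed oral drugs; intravenous
dosing counts actual administration days per cycle, so the induction →
maintenance switch (four combined doses, then 480 mg flat from one
maintenance interval after the last induction dose) falls out of the
schedule arithmetic. Pricing is per mg with no vial-wastage rounding; body
weight enters as a point mean (70 kg US, 65 kg China). The proportion of
male patients is carried as a passthrough parameter only — its mechanism in
the source model is unstated, so it deliberately has no effect (and its
tornado spread is exactly zero).

Utilities are 0.84 (PFS), 0.76 (PFS2), 0.68 (PD), 0 (death); adverse-event
disutilities are subtracted once, in cycle 1, as incidence × disutility ×
one cycle's duration. Discount rates are 3% (US) and 5% (China) annually;
willingness-to-pay $150,000/QALY (US) and $39,933.67/QALY (China, three
times per-capita GDP).

**All unit costs, adverse-event incidences and disutilities in
`make_parameter_set()` are synthetic placeholders** chosen once at
realistic public-price magnitudes (e.g. lenvatinib ≈ $69/mg US wholesale);
the original supplement's tables are not reproduced. The parameter sets
are flagged `synthetic = TRUE`. One visible consequence: with
wholesale-magnitude prices the one-way tornado is dominated by the
lenvatinib and nivolumab acquisition prices, whereas the source analysis
reported the discount rate as the top driver — a ranking that depends on
the unavailable unit costs and confidence intervals. The tests therefore
assert structural tornado properties (zero spread for parameters entering
both arms identically, monotonicity in intervention-only prices) rather
than a specific ranking.

## Uncertainty analyses

* **One-way**: each parameter alone to ±20% of base (utilities capped at
  1; discount rate varied 0–8%), rows ranked by ICER spread; failures at an
  extreme flag the row rather than dropping it.
* **Two-way**: full factorial nivolumab × ipilimumab price grid with a
  cost-effective flag at the chosen threshold.
* **PSA**: 1,000 Monte Carlo draws, every sampled parameter varied
  simultaneously — gamma for costs, beta for utilities, both
  moment-matched (`shape = (m/s)^2, scale = s^2/m`;
  `alpha = m(m(1-m)/s^2 - 1)`). The dispersion default is SD = 20% of the
  base value (the source names the families but no hyperparameters);
  an SD of 0 pins a parameter. Survival curves are held at base — the
  source does not describe survival-parameter sampling — so PSA spread
  reflects economic-parameter uncertainty only. Acceptability curves
  report exact empirical fractions of positive net monetary benefit on
  the country WTP grids (US: 50/100/150 k$; China: 22,031.53 / 39,933.67 /
  95,160.78 $).
* **Price thresholds**: bisection on a multiplier applied to one or
  several drug prices until the ICER is within 0.01% of the threshold,
  over [0.01, 3]× base; no sign change is reported as always/never
  cost-effective in range. Joint reductions in both immunotherapy prices
  need a smaller percentage cut than either single-drug reduction.
* **Scenarios**: horizons of 4/5/10/20 years, excluding adverse-event
  disutilities, restricting accrual to the PFS state, alternative PFS
  sources, and monotherapy comparators (lenvatinib or sorafenib alone).

## Numerical conventions and edge cases

* Product-limit ties: events precede censorings at equal times.
* Exponential MLE with zero events is a boundary (rate 0) and errors
  rather than returning a degenerate fit; two-parameter families require
  at least two events.
* Akaike weights with any non-finite AIC error out; the model-averaged
  survivor is clamped to [0, 1] against last-bit floating-point excess.
* Currency is written to files as fixed two-decimal strings; probabilities
  round-trip at 1e-12.
* Every pipeline run writes a manifest (config hash, seed, package and R
  versions); identical config and seed reproduce every output byte for
  byte.

## Problem sizes used in the shipped analyses

The shipped drivers and checks use trial-sized arms (335/333 and 98/110),
240-cycle horizons, 1,000 PSA draws, parameter-recovery samples of 5,000,
and reconstruction round-trips at 300 subjects/arm — the sizes the source
analysis itself implies — which keep a full run in the order of a minute.

## Known limitations

* The PFS2/PD split rests on the exponential-sojourn assumption above;
  the source's operationalization is unknowable from its text.
* Economic placeholders make the synthetic base-case ICERs illustrative
  only; they are not estimates of the published ICERs (the worked-example
  arithmetic on the published increments is, and reproduces them to the
  cent).
* PSA ignores survival-curve uncertainty by default.
* No vial wastage, dose intensity, treatment-duration caps beyond the
  schedule, or societal costs.
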