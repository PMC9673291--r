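---
title: "A partitioned survival model for first-line advanced HCC: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A partitioned survival model for first-line advanced HCC: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

## The decision problem

Sintilimab (a PD-1 inhibitor) combined with a bevacizumab biosimilar and
the oral multikinase inhibitor lenvatinib are both first-line options for
unresectable or metastatic hepatocellular carcinoma in China. They have
never been compared head to head: each was trialled against sorafenib.
`psmcea` estimates the incremental cost per quality-adjusted life-year
(QALY) of the combination over lenvatinib from the Chinese healthcare
system perspective, in 2021 US dollars, over a lifetime horizon.

## Model structure

The model is a three-state partitioned survival model (PSM) with states
progression-free (PFS), post-progression (PP) and death. Unlike a Markov
model, a PSM does not estimate transition probabilities: state occupancy
is read directly off the two endpoint curves at each cycle time $t_k$,

$$\text{PFS}_k = S_{PFS}(t_k), \qquad
  \text{dead}_k = 1 - S_{OS}(t_k), \qquad
  \text{PP}_k = \max\!\big(0,\, S_{OS}(t_k) - S_{PFS}(t_k)\big).$$

The whole cohort enters in the PFS state. The cycle length is 3 weeks —
the treatment cycle of the intravenous regimen — and the default horizon
is 522 cycles (30 years), which operationalizes "lifetime": the engine
verifies that alive occupancy is far below 0.1% well before the horizon
and that extending it changes totals by less than 0.1% (a property the
test suite enforces). Occupancy conservation ($\text{PFS} + \text{PP} +
\text{dead} = 1$) holds to $10^{-12}$ by construction and is asserted per
cycle.

Accruals use end-of-cycle occupancy by default. Half-cycle correction is
available as a flag (`half_cycle_correction`) but off by default, matching
the convention of the spreadsheet-era models this genre descends from; for
a 3-week cycle the difference is small and is dominated by the survival
calibration.

A small crossing of the curves ($S_{PFS} > S_{OS}$, possible when two
independently fitted distributions cross in the far tail) is clamped to
zero PP occupancy; a crossing larger than 0.05 raises a warning because it
signals structurally inconsistent fits rather than tail noise.

## Survival inputs

### Synthetic pseudo-IPD

The intervention arm's patient-level data are not deposited, so the
package generates pseudo individual patient data (IPD) with the structure
the analysis assumes. The generator draws latent event times from a named
parametric family, entry times uniform on the accrual window, and censors
administratively at the data cutoff: `time = min(latent, followup −
entry)`. One seed governs the whole draw and the draw order (event times,
then entry times) is fixed, so fixtures are bit-stable.

The shipped calibration is **synthetic and declared**, not published
values:

* PFS: log-normal with median 4.6 months — the published median of the
  intervention arm — and `sdlog = 1.0`. The log-scale spread of the
  fitted curve is not published anywhere; 1.0 gives the heavy right tail
  typical of immunotherapy PFS curves.
* OS: log-normal with median 18 months and `sdlog = 1.1`. The trial
  reported the OS median as *not reached*, so any OS calibration is an
  assumption; 18 months sits between the comparator trial's sorafenib
  median and the longer survival implied by the immature combination-arm
  data.
* 380 patients (the intervention arm's actual size), 12 months of
  accrual, 30 months from first entry to cutoff.

These choices were made once, are visible in
`inst/extdata/hcc_sintilimab_lenvatinib.yaml`, and can be replaced with
real IPD via `survival.ipd_paths` without touching any code. Because the
generator uses a log-normal truth, the passing model-selection tests show
the machinery works — not that log-normal is the right family for the real
trial; that conclusion belongs to the original analysts with the real
data.

### Digitization and reconstruction

For workflows starting from published figures, `digitize_km()` evaluates a
dataset's Kaplan-Meier curve on a grid with numbers at risk, and
`reconstruct_ipd()` inverts it. Because the digitized object carries the
risk count at *every* grid time (finer than a published risk table), the
inversion is deterministic: in each interval the event count is the
integer moving the running product-limit value closest to the digitized
survival, the censoring count is the remainder of the risk-table drop,
events are spread evenly over the interval's interior and censorings sit
at its right end. The product-limit factors then telescope, so the
reconstructed curve equals the digitized survival exactly at grid points;
the round-trip sup-norm tolerance of 0.02 at $n = 500$ is enforced in the
tests.

### Parametric fitting and selection

Six families are fitted to the right-censored data by maximum likelihood
(via `flexsurv`): exponential, gamma, Weibull, Gompertz, log-normal,
log-logistic. AIC ($2k - 2\ell$) and BIC ($k\ln n - 2\ell$) are recomputed
from the log-likelihood so the identities are exact. Selection takes the
minimal AIC, breaking ties by BIC and then by a fixed family order. Two
parameterization caveats are deliberate:

* The Gompertz shape may be negative, making the survivor improper with a
  plateau $\exp(\text{rate}/\text{shape}) > 0$. A plateauing Gompertz
  cannot describe a mortal cohort over a lifetime horizon, so fits whose
  plateau exceeds `gompertz_plateau_floor` (default 0.05) are excluded
  from selection.
* Log-normal and log-logistic are location/scale on log time, following
  the `flexsurv` conventions.

### The comparator arm and the hazard-ratio transform

The comparator's curves are derived from the intervention's fits by
proportional hazards on the cumulative hazard:
$S_{comp}(t) = S_{ref}(t)^{1/HR}$, where $HR$ is intervention vs
comparator (PFS 0.856, OS 0.618). Two caveats are documented rather than
hidden: the log-normal family is not closed under proportional hazards
(the transformed curve is not a log-normal), and the transform assumes
proportionality over the whole extrapolated horizon. Both are standard
practice in this model genre when only a summary HR links the arms.

### Anchored indirect comparison

The configured HRs are treated as primary inputs; the package also
re-derives the PFS contrast from the published per-trial effects through
the common sorafenib anchor as a consistency check. The Bucher contrast is
closed-form. The "Bayesian" route uses the same fixed-effect normal model
on log-HR with vague $N(0, 10^2)$ priors; with one trial per edge the
posterior is conjugate and available exactly, so the package samples the
closed-form posterior instead of running MCMC — the estimand is identical
and the agreement with Bucher within Monte Carlo error is a tested
invariant. With two trials a random-effects model is unidentifiable and
is deliberately not offered. The closed-form PFS contrast is
$0.56/0.66 \approx 0.848$, within 2% of the configured 0.856 (whose
original derivation used unpublished higher-precision inputs); the
package does not force these to agree.

## Costs, utilities and adverse events

All inputs live in the packaged YAML configuration, with base value,
range and sensitivity-analysis distribution per parameter. Choices the
source material leaves open are fixed as follows and echoed in the run
log:

* **Body weight 65 kg** for weight-based bevacizumab dosing, with
  whole-vial wastage (`ceiling` of the vial count). The scenario analysis
  halves the mg/kg dose, not the price.
* **Treatment cap**: the intravenous combination stops after 35 cycles
  (2 years) even without progression; lenvatinib is taken until
  progression.
* **Administration**: the IV arm incurs the full bundle
  (diagnosis + injection + nursing + bed) per on-treatment cycle; the
  oral arm diagnosis only.
* **Follow-up**: one full six-item panel per cycle for alive patients in
  either state.
* **Adverse events** (grade ≥ 3, incidence ≥ 5% in the source trials)
  enter as per-cycle probabilities over the first year only
  (365/21 ≈ 17.38 cycles; the fractional final cycle gets weight 0.38).
  Each event costs its management cost once and applies its disutility
  for one cycle. Per-cycle probabilities are cumulative first-year
  incidence divided by 17.38 — e.g. 23% hypertension → 1.32%/cycle.
* **End-of-life cost** is applied to each cycle's incident deaths and
  discounted at that cycle.
* **Discounting**: 5%/year compounded to the 3-week cycle,
  $(1.05)^{3/52} - 1 = 0.28\%$.
* Utilities 0.745 (PFS) and 0.678 (PP); QALY accrual per cycle is
  occupancy-weighted utility times cycle length in years, minus the
  adverse-event disutility term.

Subsequent-treatment cost is read as a *per-cycle* cost applied to PP
occupancy (it is listed alongside per-cycle quantities in the source
table; a one-off reading would be an order of magnitude smaller).

## Sensitivity analysis

**One-way (DSA).** Every parameter is set to its low and high bound (the
95% CI where published, ±20% otherwise, exactly as encoded in the
configuration; the per-cycle discount rate uses its printed 0–0.44%
range) with everything else at base, the full two-arm model is re-run,
and parameters are ranked by $|ICER_{high} - ICER_{low}|$. Bounds
producing dominance are labelled, not divided.

**Probabilistic (PSA).** Parameters are drawn jointly: beta for
probabilities, utilities and disutilities (on the magnitude, re-signed),
gamma for costs, log-normal for hazard ratios — each moment-matched with
mean at the base value and standard deviation $(high - low)/(2 \times
1.959964)$. If a beta target SD is infeasible for the mean it is clipped
with a warning. Baseline survival-curve parameter uncertainty is *not*
sampled by default — the uncertainty in the comparison enters through the
hazard ratios, mirroring the distribution list of the source analysis;
the fitted curves' covariance is retained on the fit objects for users
who want to add it. The CEAC is $P(\lambda \Delta Q - \Delta C > 0)$ on a
$0$–$50{,}000$ grid in \$500 steps (configurable), and the crossover is
the smallest grid $\lambda$ with CEAC ≥ 0.5. 5,000 iterations take well
under a minute; the whole PSA is bit-reproducible under a fixed seed.

## Numerical and testing choices

* Problem sizes used by the test suite: parameter recovery at $n = 5000$
  per family, KM round trip at $n = 500$, moment-matching checks at
  50,000 draws, property checks on toy two-state traces with
  hand-computed accruals, and an independent scalar-loop re-implementation
  of the trace that must agree with the vectorized engine to $10^{-9}$.
* Sampling-based assertions use tolerances of 3–4 Monte Carlo standard
  errors at the stated sizes.
* The engine is fully vectorized over cycles; a 522-cycle two-arm run
  costs about a millisecond, which is what makes the brute-force DSA and
  5,000-iteration PSA cheap.
* ICER arithmetic on the published per-arm totals (ΔQALY 0.493,
  ΔC \$12,065, ICER ≈ \$24.5k; scenario ΔC \$3,715, ICER ≈ \$7.5k) is
  reproduced by `incremental_summary()` from the rounded printed inputs.

## Known limitations

* The synthetic calibration reproduces the *shape* of the decision
  problem, not the source trial's exact curves; absolute base-case
  results shift with the declared OS assumption.
* Proportional hazards over a lifetime horizon is untestable from the
  available summaries and is likely optimistic for immunotherapy tails.
* No treatment crossover, cure fractions, covariate adjustment or
  time-varying utilities beyond the adverse-event window; direct medical
  costs only.
* The two-trial star network cannot detect inconsistency or
  heterogeneity; the Bayesian route is a re-derivation, not independent
  evidence.
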