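---
title: "Modelling weekly air-quality state transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling weekly air-quality state transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqmarkov)
```

## The model

`aqmarkov` treats a country's weekly air-quality category as a
three-state continuous-time Markov chain observed at discrete panel
times. The states are Good (1, AQI ≤ 150), Unhealthy (2,
150 < AQI ≤ 200) and Very Unhealthy (3, AQI > 200); the boundary values
belong to the lower state, following the printed inequalities of the
classification. All three states are transient — air quality can always
deteriorate or improve — so all six off-diagonal transition intensities
are estimated. Rare direct jumps (Good ↔ Very Unhealthy between two
weekly readings) are left as free parameters rather than structural
zeros: the data decide how small they are, and their standard errors
honestly reflect how little the data say.

The transition intensity from state $r$ to $s$ for a subject with
covariate vector $z$ is log-linear (proportional intensities):

$$q_{rs}(z) = \exp(\log q_{rs} + \beta_{rs}^\top z), \qquad
  q_{rr}(z) = -\sum_{s \ne r} q_{rs}(z).$$

Region enters through indicator columns (Asia, Africa) with Europe as
the reference, so $\exp(\beta_{rs})$ is the hazard ratio of a region
effect on one specific transition. Three quantities derive from the
fitted generator $\hat Q(z)$:

* **Transition probabilities** $P(t) = e^{tQ}$, the chance of being
  found in state $s$ after $t$ weeks given state $r$ now. This is the
  panel-observation quantity: the chain may leave and return within the
  window, and the matrix exponential sums over all such unobserved
  paths.
* **Mean sojourn times** $-1/q_{rr}(z)$, the expected length of a single
  stay in state $r$, in weeks. Standard errors come from the delta
  method through the full parameter covariance.
* **Persistence curves**, the diagonal $P(t)_{rr}$ for $t = 1,\dots,10$
  weeks. We use the diagonal of $P(t)$ deliberately — "probability of
  remaining" for weekly-sampled data is usually read this way even
  though the phrase is overloaded (it is not the probability of never
  leaving, which would be $e^{-t\,q_{r\cdot}}$).

### Likelihood and why panel observation matters

Weekly readings never show when a transition happened, only the states a
week apart. The likelihood is therefore a product over consecutive
within-country week pairs of matrix-exponential entries,

$$\ell = \sum_{\text{pairs}} \log P(\Delta t;\, z)_{s_t,\, s_{t+1}},$$

with $\Delta t = 1$ week for adjacent panel rows. Internally the panel
is reduced to transition-count matrices per (region, $\Delta t$) group,
so one likelihood evaluation needs only one matrix exponential per
group regardless of panel size — this is what makes the recovery
simulations below cheap.

## Fitting: numerical choices

* **Parameterisation.** Baseline intensities are estimated on the log
  scale, which enforces positivity without constraints; covariate
  effects add linearly on that scale.
* **Initialisation.** Crude rates $q^0_{rs} = n_{rs} / T_r$ (observed
  transitions over weeks spent at risk in $r$), floored at $10^{-3}$ so
  unobserved transitions start finite; coefficients start at zero.
* **Optimizer.** Bounded quasi-Newton (L-BFGS-B), relative
  log-likelihood tolerance about $2\times 10^{-9}$, projected-gradient
  tolerance $10^{-5}$, at most 500 iterations. Bounds keep parameters in
  a range weekly data can speak to: rates in $[10^{-8}, 50]$ per week,
  coefficients in $[-20, 20]$. A transition never observed anywhere in
  the panel drives its baseline to the lower bound and is flagged
  non-identified rather than silently reported.
* **Overflow guard.** At extreme rates the scaling-and-squaring matrix
  exponential can overflow into a matrix that is no longer stochastic;
  any such result is treated as likelihood $-\infty$, which keeps the
  optimizer out of that artifact region. Without the guard a fit can
  "improve" into numerical garbage where spurious entries exceed 1.
* **Covariance.** Observed information by central finite differences
  (relative step $10^{-5}$) at the optimum, inverted directly; if the
  information matrix is singular or produces negative variances the
  Moore–Penrose pseudo-inverse is used and the fit is flagged
  degenerate. Rare transitions then show the enormous Wald intervals
  they deserve instead of being suppressed.
* **Confidence level.** 95% throughout, normal quantile 1.959964.

## The time-homogeneity check

`time_homogeneity_check()` splits the panel at its midpoint week, fits
the model on each half and once jointly, and reports
$2(\ell_\text{early} + \ell_\text{late} - \ell_\text{joint})$ against a
$\chi^2$ with one degree of freedom per free parameter. One subtlety:
the week pair spanning the midpoint belongs to neither half, so the
joint fit treats each half as its own series segment. Joint and split
fits then use exactly the same transition pairs, which is what makes
the statistic properly nested — including the spanning pair only in the
joint likelihood inflates the statistic by roughly two units per
subject and wrecks the null calibration. Halves with fewer than a dozen
transition pairs are flagged underpowered instead of tested.

## Preprocessing decisions

* **Breakpoint table.** The AQI map is a configurable JSON table of
  concentration/index segments. The default is the long-standing US EPA
  PM2.5 table (Good/Moderate cut at 12.0 µg/m³), with adjacent segment
  ends made to touch so the map is continuous and strictly increasing —
  which also makes it exactly invertible, something the daily-data
  simulator relies on. The 2024 EPA revision (9.0 µg/m³ cut) ships as an
  option: public AQI platforms followed one or the other during 2024,
  and which one applied to any given scrape is not recoverable, so the
  choice is configuration, not code. Concentrations above the top
  segment extrapolate the last slope rather than failing.
* **Order of operations.** Daily PM2.5 is converted to daily AQI first,
  then averaged within weeks. Averaging concentrations first and
  converting once would differ slightly (the map is piecewise linear,
  not linear).
* **Week definition.** Consecutive 7-day blocks from each country's
  first date — not ISO calendar weeks — which is the only definition
  that yields exactly 40 weeks over a January–September window.
* **Sparse weeks.** A week with at least 4 valid days keeps the mean of
  its available daily values. Sparser weeks are filled by linear
  interpolation between the nearest valid weekly neighbours
  (nearest-value carry at the series edges) and flagged `imputed`. The
  threshold of 4 is a majority-of-days rule; the linear rule is the
  simplest defensible interpolator, and since downstream analysis only
  uses the categorical state, small differences between interpolators
  rarely change a week's category. A subject with no valid week at all
  is an error, not an imputation target.

## What the synthetic generator emulates

`sim_config()` defaults describe a study-shaped panel: 19 countries —
9 Asia, 3 Africa, 7 Europe — observed at 40 weekly times. Each region
has its own true generator, chosen so the implied mean sojourn times
match the magnitudes reported for real weekly AQI panels (Asia: 6.80,
6.64, 3.36 weeks for states 1–3; Africa: 4.57, 2.66, 0.95; Europe:
7.68, 0.90, 0.68), and so the Asia Unhealthy→Good rate is 0.09 times
Europe's — slow recovery in Asia, quick recovery in Europe, short
Very Unhealthy episodes in Africa. Within each row, the exit rate is
split across destinations so that drastic two-category jumps are rare,
matching how air quality actually moves.

Trajectories are simulated exactly (exponential holding times, embedded
jump chain) and read at integer weeks, so a simulated panel is a true
draw from the model being fitted — no discretisation bias. Initial
states are drawn from each region's stationary law to avoid start-up
transients (overridable, and required when a supplied generator is
reducible, e.g. a two-state toy chain). The optional daily layer draws
a latent weekly AQI uniformly within the state's band, adds Gaussian
daily noise (default sd 10 AQI units, truncated at zero), inverts the
breakpoint map to PM2.5, and drops days independently at a configured
rate — exercising the aggregation and imputation path end to end.

What the generator does **not** emulate: seasonality, meteorology,
serial dependence beyond the Markov structure, and spatial correlation
between countries. Passing recovery tests therefore show that the
estimator recovers the truth *when the model holds*; they cannot show
that real air-quality dynamics are Markovian. Note also that at extreme
missing-day rates (most weeks below the 4-valid-day threshold for every
week of a subject) preprocessing fails by design — there is nothing
left to interpolate from.

## Validation scales

The recovery and calibration studies in the test suite use problem
sizes chosen to make the asymptotic approximations they test
meaningful while keeping each study a few minutes at most: parameter
recovery uses 50 replicates of 100 subjects × 100 weeks across two
regions; sojourn coverage uses 40 replicates at the study's own shape
(19 subjects × 80 weeks) plus one large fit (120 × 150); hazard-ratio
recovery uses 90 + 90 subjects × 120 weeks; Wald coverage uses 200
replicates of a two-transition model at 30 + 30 subjects × 50 weeks.
The acceptance script's headline refits use 200 × 200 (sojourn) and
100 + 100 × 150 (hazard ratio).

## A short tour

```{r tour, eval = FALSE}
panel <- simulate_panel(sim_config(), seed = 7)
fit <- fit_msm(panel, reference = "Europe")

tidy(fit, exponentiate = TRUE)   # rates and hazard ratios with CIs
sojourn_times(fit)               # weeks in state, with SEs
predict_transitions(fit, weeks = c(1, 2, 4), region = "Asia")
autoplot(fit)                    # persistence curves
time_homogeneity_check(panel)

bundle <- report_bundle(fit, counts = count_transitions(panel))
render_report(bundle, "report")  # CSVs + manifest.json
```

## Known limitations

* Time-homogeneous intensities only; no time-varying covariates,
  semi-Markov holding times, or misclassification (hidden Markov)
  layers.
* Wald intervals on the log scale; for transitions observed a handful
  of times profile or bootstrap intervals would behave better, and the
  reported intervals can span many orders of magnitude — by design they
  are shown, not truncated.
* The covariance comes from a finite-difference Hessian; with many
  near-boundary parameters the pseudo-inverse fallback flags, but does
  not repair, weak identification.
* The Markov assumption itself is not tested beyond time-homogeneity;
  dependence on earlier states would need a different model class.
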