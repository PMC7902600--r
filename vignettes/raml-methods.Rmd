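---
title: "A stochastic two-hit model of radiation-induced AML in CBA/H mice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic two-hit model of radiation-induced AML in CBA/H mice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramlsim)
```

## The model

Male CBA/H mice develop radiation-induced acute myeloid leukemia (rAML)
almost exclusively through a two-hit sequence: an interstitial deletion on
chromosome 2 (del2) removes one copy of *Sfpi1* (coding for PU.1), and a
later point mutation at codon R235 inactivates the remaining allele, creating
a malignant founder cell. `ramlsim` turns this biology into a per-mouse
stochastic simulation with four layers.

**1. Acute exposure (deterministic closed forms).** A dose $D$ (Gy) produces
on average $L(D) = \alpha D + \beta D^2$ lethal lesions per hematopoietic
stem cell; clonogenic survival is $S(D) = e^{-L(D)}$. A fixed fraction
$\mu_{del2}$ of lethal-lesion production instead yields viable del2 cells, so
at the end of an (effectively instantaneous) exposure the expected healthy
and del2 cell numbers are

$$H(D) = H_0\,e^{-L(D)(1+\mu_{del2})}, \qquad
  I(D) = H(D)\left(e^{\mu_{del2} L(D)} - 1\right),$$

with $H_0 = 15670$ stem cells per mouse. These identities hold exactly for
any constant dose rate, not only in the acute limit — the during-exposure
kinetics can be rewritten in terms of accumulated lesions — which is also how
the test suite validates them against an independent ODE integration at a
finite dose rate. They satisfy the conservation identity
$H(D) + I(D) = H_0 S(D)$, and $I(D)$ peaks where
$L(D) = \log(1+\mu_{del2})/\mu_{del2}$ (about 2.67 Gy at the default
parameters, where $I \approx 280$ cells). Each simulated mouse seeds
$I(0) \sim \mathrm{Pois}(I(D))$ intermediate cells; spontaneous (background)
del2 formation is disregarded, so an unexposed mouse can never develop rAML
in this model.

**2. Post-exposure jump process.** Three first-order channels act on the
intermediate ($I$) and proliferating ($I_p$) del2 populations:
selection into the proliferating pool at rate $I/T_{pool}$
($T_{pool} = 9$ months), division at rate $b\,I_p$, and malignant
transformation at rate $\mu_{Sfpi1} I_p$. The first transformation event ends
the simulation at $t_{M=1}$; no death or background gain of $I$/$I_p$ cells
occurs after exposure (killing acts only through the initial condition).
Whether the transformation consumes an $I_p$ cell is immaterial because
nothing after $t_{M=1}$ is used.

**3. Competing mortality.** Each mouse draws an other-cause survival time
$t_s$ from a skew-normal distribution with location
$\xi = 786.43 - 17.45\,D$ days, scale $\omega = 178.60$ days and shape
$-1.013$, reproducing a left-skewed unexposed distribution (mean 685 d, SD
147 d, skewness $-0.141$) and a mean of about 580 d after 6 Gy. Sampling
uses the exact two-normal representation; the negligible negative mass
(~$10^{-6}$) is rejected and redrawn rather than clamped, so no atom appears
at zero. The distribution is not otherwise truncated — at these parameters
the choice is numerically irrelevant, and closed-form moments therefore
ignore it.

**4. Diagnosis.** rAML is diagnosed at $t_{AML} = t_{M=1} + T_{lag}$
($T_{lag} = 22$ weeks) provided $t_{AML} \le t_s$. Internally each mouse is
simulated only to $t_s - T_{lag}$: a malignant cell arising later can never
be diagnosed, so the early stop is provably outcome-equivalent (and the
suite checks the two horizon modes agree pathwise under common seeds).

All rates are per day; $T_{pool} = 9 \times 365.25/12 = 273.94$ d and
$T_{lag} = 22 \times 7 = 154$ d, since the calibrated rates are daily while
the literature quotes months and weeks. Reported onset times use weeks
$=$ days$/7$ exactly.

## Simulation engines

The jump process runs on one of two engines, selectable everywhere:

* `exact_ssa` — the exact next-event (Gillespie) algorithm for the two
  state-changing channels. The terminating mutation channel changes no
  state, so both engines integrate its cumulative hazard
  $\Lambda(t) = \mu_{Sfpi1}\int_0^t I_p\,\mathrm{d}s$ against a pre-drawn
  $\mathrm{Exp}(1)$ threshold; with piecewise-constant $I_p$ the crossing
  time is exact (time-change theorem).
* `adaptive_tau` — species-based adaptive tau-leaping: each leap $\tau$ is
  capped so every population changes by at most a fraction
  $\varepsilon$ (default 0.01) in expectation and in standard deviation,
  channel counts are Poisson, leaps that would drive a population negative
  are halved and redrawn, and the engine falls back to exact steps whenever
  any nonzero population is below `switch_threshold` (default 10 cells) or a
  leap would not beat ~10 exact steps.

With $\varepsilon = 0.01$ the leap criterion only engages for populations
above roughly a thousand cells, so at the default parameters most
trajectories are exact; the tau machinery earns its keep for large
proliferating pools and permissive $\varepsilon$. The suite verifies the two
engines agree — exactly under permanent fallback with common seeds, and
statistically (cohort incidence and onset at 1, 3 and 6 Gy, Yule-process
means) when genuine leaping is forced with $\varepsilon = 0.1$.

Each mouse gets an independent counter-seeded xoshiro256++ substream derived
from the master seed, while the Poisson seeding and mortality draws use R's
stream under the same seed; cohorts are therefore reproducible bit-for-bit
from `(configuration, seed)` and independent of execution order. Mice whose
Poisson draw is zero skip the engine entirely, which makes the
multi-million-mouse low-dose runs cheap.

## Calibration

`raml_fit()` estimates $(\alpha, \beta, \mu_{del2}, \mu_{Sfpi1}, b)$ from an
incidence dataset: 20 records of per-study incidence at 0.75/1.5/3/4.5/6 Gy
(40–61 mice each, four studies per dose) plus one mean onset time $\tau$ at
4.5 Gy. The cost is the weighted residual sum of squares

$$C(\mathbf p) = \sum_{i=1}^{n} w_i\,(A_i - \hat A_i(\mathbf p))^2
  + \left(\frac{\sum_i w_i A_i}{n\,\tau}\,(\tau - \hat\tau(\mathbf p))
    \right)^2,$$

with $w_i$ each record's share of the total mouse count; the onset residual
is scaled so both data types enter on comparable scale. Since the weights
sum to one, $\sum_i w_i A_i$ is simultaneously the weighted mean incidence.

Choices worth knowing about:

* **Log-scale optimization.** The constants span four orders of magnitude
  and must stay positive, so the optimizers work on $\log \mathbf p$.
* **Global then local.** Simulated annealing (`optim(method = "SANN")`, a
  Gaussian proposal with SD 0.4 on the log scale, temperature 1) explores
  from the conventional start (0.01, 0.01, 0.01, 2.4e-6, 2.4e-3); its
  optimum seeds a Nelder–Mead refinement. Budgets (annealing evaluations,
  Nelder–Mead iterations, mice per cohort per cost evaluation) are
  configurable; the defaults (200/150/500) are desk-scale and recover each
  constant within its bootstrap uncertainty span in the suite's synthetic
  experiment, while production fits would use orders of magnitude more.
* **Common random numbers.** Every cost evaluation reuses the same
  simulation seeds across candidate parameter vectors, turning the
  stochastic objective into a fixed deterministic function — without this,
  Nelder–Mead stalls on Monte-Carlo noise at small cohort sizes. Parameter
  regions where the 4.5 Gy cohort yields fewer than two diagnoses have no
  defined $\hat\tau$ and receive a large finite penalty.
* **Residual bootstrap.** `raml_bootstrap()` forms replicate datasets from
  the best-fit output plus incidence residuals resampled with replacement
  (clamped to $[0,100]$); the single onset residual is reapplied with a
  random sign, a choice the underlying method leaves open for a one-element
  residual set. Replicates are refit by Nelder–Mead only, from the best-fit
  start, and bias-corrected (BC) percentile intervals summarize the
  replicate estimates. Zero residuals reproduce the point estimate exactly,
  degenerating the intervals — a property the suite asserts.

## The synthetic incidence generator

The historical incidence tables behind the published calibration are not
redistributable, so `synthesize_dataset()` generates stand-in data at the
study design: it simulates the model at each design dose (default $10^4$
mice) to obtain a true incidence probability, draws each study's observed
count from $\mathrm{Binomial}(n_{mice}, p)$ with $n_{mice}$ uniform on
40–61, and takes the onset reference from the 4.5 Gy cohort. It reproduces
the sampling noise and design of the historical experiments, but *not*
inter-study heterogeneity (dosimetry drift, diagnostic criteria, husbandry),
which is why passing recovery tests demonstrate internal consistency of the
estimator, not fidelity to the historical measurements themselves.

## Low-dose extrapolation and the LDEF

`fit_dose_response()` fits three no-intercept forms to incidence
percentages — linear-quadratic $\alpha D + \beta D^2$, linear $\alpha_L D$,
and del2-proportional $c\,I(D)$ — optionally on log incidence, which
down-weights the large-incidence points; zero-incidence points cannot enter
a log fit and are dropped with a warning (pseudo-counts would bias the
slopes). Raw fits and single-coefficient log fits are closed-form least
squares; the log-scale LQ fit uses `nls`. Fit quality on a low-dose grid is
scored by $RSS_{log} = \sum (\log A_{obs} - \log A_{pred})^2$.

`extrapolation_study()` reruns the published design at configurable scale:
only high-dose (0.25–1 Gy) simulated incidence is made available for
fitting, and every fit is scored against the simulated low-dose
($\le 0.2$ Gy) response. The low-dose effectiveness factor
$LDEF = 1 + (\beta/\alpha) D_x$ (evaluated at $D_x = 1$ Gy from the LQ fit
of the matching transform) divides the linear extrapolation. At desk scale
the qualitative findings are robust: the del2-proportional form beats the
LQ form, both beat the uncorrected linear fits, and the LDEF correction
improves the linear fits substantially under either transform.

Two numerical notes. First, the proportionality constant $c$ depends mildly
on the fitting window: fitted against the high-dose estimates it comes out
near 0.107, fitted directly on the low-dose grid near 0.114, because the
per-del2-cell diagnosis probability declines slightly with dose (shorter
survival leaves less time for the second hit). Second, grids are
`seq(0.02, 0.20, by = 0.02)` Gy (low) and `0.25, 0.5, 0.75, 1` Gy (high) —
the published account states the ranges but not the grids.

## Problem sizes and tolerances

Package defaults and the bundled analysis script use cohort sizes chosen so
every target quantity's Monte-Carlo error sits well inside its comparison
tolerance: $10^5$ mice for the 2.6 Gy peak (binomial SE ≈ 0.13 pp),
$2\times10^5$ per low-dose point ($2\times10^6$ in all; the fitted
$\alpha$ then carries ~3–5% SE against a ~10% tolerance), $10^4$ at 6 Gy for
mean survival (SE ≈ 0.2 wk), and $10^5$-draw checks of the mortality
moments against their closed forms. Closed-form identities are asserted to
$10^{-10}$ relative; quantities derived from constants printed to three
significant figures get ~0.5% slack.

## Limitations

* Only the del2 → R235 pathway is modeled; alternative routes
  (Flt3-ITD, Kras, *Sfpi1* promoter methylation) and human translation are
  out of scope.
* Only acute exposure is exercised; protracted or fractionated schedules
  (and DREF/DDREF analyses) would need the finite-dose-rate kinetics on the
  simulation path rather than only in the test oracle.
* Onset summaries condition on diagnosed mice; the onset-polynomial value at
  0 Gy (80.8 wk) is an extrapolation of the cubic fit, not a model
  prediction, since the model produces no rAML at exactly zero dose.
* Mortality parameters are fixed inputs, not fitted, and rAML deaths are
  assumed to occur exactly at diagnosis.
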