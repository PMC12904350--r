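---
title: "Simulating dichotomous-item adaptive tests: model, choices, and scope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating dichotomous-item adaptive tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptcat)
```

## The measurement model

`adaptcat` simulates adaptive administration of dichotomously scored
(correct/incorrect) items calibrated under the three-parameter logistic
(3PL) model. The probability that a respondent at latent trait $\theta$
answers item $j$ correctly is

$$P_j(\theta) = c_j + (1 - c_j)\,
  \frac{1}{1 + e^{-a_j(\theta - b_j)}},$$

with discrimination $a_j > 0$, difficulty $b_j$, and lower asymptote
$0 \le c_j < 1$ absorbing guessing on multiple-choice items. The trait is
on a standardized scale (population mean 0, SD 1). The model assumes
unidimensionality and local independence — item responses are independent
given $\theta$ — which is what licenses the multiplicative posterior
update below. Items violating these assumptions (poor loadings, local
dependence, differential functioning) are assumed to have been screened
out during calibration; calibration itself is out of scope here, and item
parameters are taken as known inputs.

The Fisher information of item $j$,

$$I_j(\theta) = a_j^2\,\frac{Q_j}{P_j}
  \left(\frac{P_j - c_j}{1 - c_j}\right)^2, \qquad Q_j = 1 - P_j,$$

reduces to the familiar $a^2 P Q$ at $c = 0$ and vanishes in both tails:
a respondent answering everything correctly (or incorrectly) provides
almost no information, which is the mechanism behind the tail behaviour of
the stopping rules discussed below.

## Scoring: EAP on a quadrature grid

Scoring is Bayesian. The posterior over $\theta$ is carried on a grid of
`n_grid_points` equally spaced points spanning `[theta_min, theta_max]`
(defaults: 49 points on $[-4, 4]$), initialized at a Normal(0, 1) prior.
Each response multiplies the weights by the Bernoulli likelihood and
renormalizes; the point estimate is the posterior mean (EAP) and the
reported standard error is the posterior SD. Interim (mid-test) and
full-length scores use identical machinery, so the full-bank adaptive run
and the non-adaptive full-length score agree to machine precision — a
property the test suite asserts at $10^{-12}$.

Two numerical choices matter:

* **Trapezoid prior weighting.** Grid weights are the prior density times
  trapezoid-rule quadrature weights (the two endpoints halved). With plain
  density weights, the discrete posterior disagrees with a 10,001-point
  reference quadrature by up to $5\times10^{-3}$ in EAP/SD whenever an
  extreme response pattern piles posterior mass against a grid boundary —
  an $O(h)$ endpoint effect. Trapezoid weighting removes it; the 49-point
  default then tracks the dense reference within about $4\times10^{-4}$
  over random 22-item banks and patterns (asserted at $10^{-3}$).
* **Truncation.** Renormalizing the prior on $[-4, 4]$ shaves tail mass,
  so the on-grid prior SD is $\approx 0.9996$, not exactly 1. Estimates
  are bounded by the grid range by construction; respondents beyond it are
  pulled inward, one reason precision degrades in the tails.

The logistic is evaluated via `stats::plogis()`, which does not overflow
for large $|a(\theta - b)|$, and the full-length posterior is accumulated
with stepwise renormalization so 22-item products cannot underflow.
Degenerate inputs fail loudly: items with $a \le 0$ or $c \ge 1$,
incomplete or non-binary response rows, and configurations with
`min_items > max_items` are rejected at construction.

## Item selection

The default selector is **maximum posterior weighted information
(MPWI)**: each unadministered item is scored by
$\sum_k I_j(\theta_k) w_k$, its information averaged against the current
posterior, and the maximizer is administered. MPWI has the strongest
measurement-precision record among common selectors and uses the whole
posterior rather than a point estimate; maximum information at the
current EAP point is available as `method = "max_info_at_point"` for
comparison.

Before any response exists the posterior is just the prior, and two
first-item conventions circulate: maximum Fisher information at
$\theta = 0$ (the conventional "first item at theta 0" rule, our
default), and MPWI under the prior. For a symmetric prior centred at 0
they almost always pick the same item; both are implemented as explicit
policy options rather than guessing which a given legacy tool means.
Ties are broken by lowest bank index, making every simulation
deterministic and replays byte-identical. There is no exposure control or
content balancing — deliberate: the design this workbench evaluates is a
bare prototype, and constraining selection would change the very
efficiency numbers being studied.

## Stopping rules

Two rules are crossed in scenario grids:

* **Primary (SE rule):** stop once the posterior SD is at or below
  `se_threshold` (conventional values 0.50 and 0.45, i.e. marginal
  reliabilities of roughly 0.75 and 0.80).
* **Secondary (length cap):** stop after `max_items` items (15, 18, or
  the full bank).

Stopping is evaluated only after a response is absorbed, never before the
first item, and when both rules would fire on the same item the SE rule
takes precedence, so each session is classed as exactly one of
`se_reached` / `max_items`. `min_items` defaults to 1: with a unit-SD
prior, the SE after zero items exceeds any sensible threshold anyway, so
the floor only guards degenerate configurations; observed minimum lengths
should emerge from the data, not from a configured floor. Cap-terminated
sessions concentrate in the tails of the theta distribution — the
diagnostics in `secondary_rule_diagnostics()` and the per-step
`se_reduction_analysis()` (default threshold: an SE drop greater than
0.01 from one more item) quantify how much precision the cap actually
costs and for whom.

## The synthetic cohort: what it emulates, and what it does not

Real calibration matrices are rarely distributable, so
`synthetic_spec()` defines a generator whose defaults mirror a typical
calibration study for a 22-item, four-option multiple-choice knowledge
instrument administered to 1000 respondents:

| quantity | default | rationale |
|---|---|---|
| $\theta$ | Normal(0, 1) | the standardized trait metric |
| $a$ | LogNormal(log 1.2, 0.35) on [0.5, 3] | positive, right-skewed; floor reflects screening out weak items |
| $b$ | Normal(0, 1) on [−3, 3] | difficulties spread over the trait range |
| $c$ | Beta(5, 20), mean 0.2 | empirical lower asymptotes of 4-option items sit slightly below the nominal 0.25 guessing rate |

Responses are independent Bernoulli draws from the 3PL at the
respondent's true $\theta$; everything is reproducible from a recorded
seed. The generator emulates the *structure* of calibration data, not any
particular instrument: it draws item parameters independently (no
difficulty–discrimination correlation, no content-domain clustering),
produces no missingness, and its respondents answer exactly according to
the model (no carelessness, local dependence, or differential
functioning). Passing tests on synthetic cohorts therefore demonstrate
that the algorithmic pipeline is correct and that qualitative patterns
(threshold dominance, tail concentration, the adaptive-over-static
ordering) hold under model-faithful data — not that a specific real
instrument will reproduce any particular median length or RMSE. Synthetic
banks drawn from these defaults are also, on average, less informative
than a well-calibrated operational bank, so simulated tests run somewhat
longer than published operational figures; scenario comparisons remain
meaningful because all cells share the bank.

## Evaluation conventions

* **Correlation by length** (`correlation_by_length()`): at step $k$,
  respondents who already stopped contribute their final theta (carried
  forward), matching what a deployed CAT capped at $k$ items would
  report. The restriction to respondents still active at step $k$ is
  available via `carry_forward = FALSE`; the two can differ noticeably
  once many respondents have stopped.
* **Summaries** use the population-SD denominator ($n$, not $n-1$) and
  linearly interpolated percentiles (R's default type 7), stated so that
  outputs are bit-reproducible.
* **RMSE** is always against the full-length EAP of the same response
  matrix, the natural reference for "what would the full form have said".
* **Static short forms** (`compare_static_short_form()`) are scored with
  the same grid and prior on the fixed subset only, so adaptive-vs-static
  comparisons differ only in item choice.

## Problem sizes

The test suite exercises the full 1000 × 22 default cohort for the
scenario-grid properties and end-to-end equivalences (a post-hoc run of
one scenario takes well under a second), reduced cohorts of 30–400
respondents for module-level properties, and 100-draw randomized checks
against dense-grid and brute-force oracles. `scripts/acceptance.R` runs
the complete 2 × 3 design plus an exhaustive reference run in a few
seconds.

## Known limitations

* Dichotomous 3PL only; no polytomous models.
* No content balancing or item-exposure control (see above).
* No handling of missing responses in post-hoc mode — the replayed matrix
  must be complete.
* Item parameters are inputs; calibration, fit assessment and
  differential-functioning screening belong upstream.
* EAP with a fixed Normal(0, 1) prior shrinks extreme respondents toward
  the center; combined with low tail information this makes tail scores
  both biased inward and imprecise, which is precisely why the secondary
  stopping rule and its diagnostics exist.
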