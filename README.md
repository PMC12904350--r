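# adaptcat

Computerized adaptive testing (CAT) simulation for dichotomously scored
item banks under the three-parameter logistic (3PL) item response model.

A fixed-length knowledge test wastes items: most respondents answer many
items that tell us little about their standing. A CAT instead selects each
next item from a calibrated bank based on the respondent's current latent
trait estimate, and stops as soon as the estimate is precise enough.
`adaptcat` is a workbench for deciding, before deployment, how such an
adaptive test should be configured: it replays a complete, previously
collected response matrix through the adaptive algorithm ("post-hoc
simulation"), crosses candidate stopping rules, and quantifies the
efficiency/precision trade-off of each scenario. It is aimed at
psychometricians and health-measurement researchers evaluating adaptive
short forms of patient-reported or knowledge instruments.

## The model and the algorithm

Each item is a triple (a, b, c) under the Birnbaum 3PL model for the
probability of a correct response at latent trait θ (standardized scale,
mean 0, SD 1):

    P(θ) = c + (1 − c) / (1 + exp(−a(θ − b)))

Scoring is Bayesian on a quadrature grid over θ ∈ [−4, 4] with a
Normal(0, 1) prior: after each response the posterior is updated with the
Bernoulli likelihood, the **EAP** (expected a posteriori) estimate is the
posterior mean, and the reported standard error is the **posterior SD**.
Item selection uses **maximum posterior weighted information (MPWI)**: the
candidate maximizing Fisher information

    I(θ) = a² (Q/P) ((P − c)/(1 − c))²,  Q = 1 − P

integrated against the current posterior. The first item is the bank's most
informative item at θ = 0. Administration stops when the SE reaches a
threshold (primary rule) or a maximum test length is hit (secondary rule).

Because calibration response matrices are rarely public, the package ships
a seeded synthetic generator (1000 respondents × 22 four-option items by
default, θ ~ N(0,1), a ~ truncated log-normal, b ~ truncated normal,
c ~ Beta(5,20)) so every analysis is runnable end to end.

## Worked example

```r
library(adaptcat)

spec   <- synthetic_spec(seed = 42)               # 1000 x 22 cohort
bank   <- generate_item_bank(spec)
thetas <- generate_thetas(1000, seed = 43)
X      <- generate_response_matrix(thetas, bank, seed = 44)

run <- run_posthoc_simulation(X, bank,
                              cat_config(se_threshold = 0.50, max_items = 15))
run
#> Post-hoc CAT run: 1000 respondents, SE threshold 0.50, cap 15 items; mean length 12.46, median 13

run$results[[1]]
#> CAT session r0001: 15 items, final theta -0.215 (SE 0.531), stopped by max_items

s <- summarize_scenario(run)
correlation_by_length(run, k = 9)        # 0.948
secondary_rule_diagnostics(run)$n_max_items   # 338
```

Reading the numbers: the median respondent needed 13 of the 22 items to
reach SE ≤ 0.50, and a 9-item adaptive score already correlates 0.948 with
the full 22-item score. The 338 sessions that ran into the 15-item cap
instead of the SE rule sit disproportionately in the tails of the theta
distribution (56% with |θ̂| > 1), where dichotomous items carry little
information — exactly the population a deployment would flag for the full
form. `run_scenario_grid()` crosses SE thresholds {0.50, 0.45} with caps
{15, 18, 22} and returns one such summary row per cell;
`se_reduction_analysis()` reports, per test length, how many respondents
would still gain more than 0.01 SE from one more item.

A command-line driver wrapping the same functions is installed at
`system.file("cli", "adaptcat.R", package = "adaptcat")` with subcommands
`generate`, `run` and `evaluate`.

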