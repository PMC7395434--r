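---
title: "Modelling collective-risk dilemmas: game mechanics, behavioural types, and the analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling collective-risk dilemmas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crdgame)
```

## The game

The threshold public-goods game under collective risk works as follows.
Each of $n$ players (group sizes 3, 7 and 11 are the study's conditions;
any odd size is supported) holds an endowment of 40 capital units and, in
each of 10 rounds, invests 0, 2 or 4 units into a common pool. The group
target is

$$T = f \cdot R \cdot n = 2 \times 10 \times n,$$

with $f = 2$ the *fair share*: if everyone invests 2 units every round the
target is met exactly. Success converts each player's savings to money at
¥2 per unit on top of a ¥15 show-up fee; failure triggers a loss lottery
that wipes all savings with probability $\tfrac12$. Payouts are therefore
bounded in [¥15, ¥95], with both extremes attainable (a player saving the
full endowment inside a successful group; any member of a wiped group).

Two modelling choices deserve comment:

* **Lottery granularity.** The game's framing ("your group could lose
  everything") suggests one shared draw, while the rule statement is
  per-volunteer. The default is a single Bernoulli draw per failing group;
  `game_config(per_player_lottery = TRUE)` switches to independent draws.
  Expected payouts are identical; only the within-group payout correlation
  differs.
* **Timing is not modelled.** The human experiment allotted decision and
  reading windows (30–50 s); decisions here are collected atomically per
  round, since timing pressure affects people, not the mechanism.

The running diagnostic is the surplus series
$s(r) = \sum_{\rho \le r} I(\rho) - f\,n\,r$: zero along the all-fair-share
path, $s(R) = \text{total} - T$ at the end, so success is $s(R) \ge 0$.

## Communication

Treatment groups answer up to five yes/no questions between rounds: Q1–Q2
(target optimism, current-round satisfaction) from round 1, Q3–Q4 (overall
satisfaction, demand for more investment) from round 2, and Q5 (perceived
loss risk) from round 6. Only the group majority's answer per question is
displayed; groups are odd-sized precisely so a strict majority exists.
Answers are collected after the round's results display and inform the next
round. Missing answers (human data contain timeouts) are treated as
abstentions and excluded from the count; a resulting tie resolves to "no"
and is flagged, since the display software warned but the final handling is
not documented.

## Generative behavioural types

Three behavioural types summarise play: *cooperators* hover around the fair
share, *free riders* invest little, *altruists* invest above the norm and
ramp up. The published summaries are population means over all rounds
(1.96, 0.77, 2.96 units) and linear round trends (slopes 0.080, −0.022,
0.152 units·round⁻¹). The generative policy is the simplest model matching
both moments exactly: expected investment linear in the round,

$$m_k(r) = a_k + b_k r, \qquad a_k = \bar m_k - 5.5\, b_k,$$

(5.5 is the mean of rounds 1–10), and the draw on the menu $\{0,2,4\}$ is
$2\,\mathrm{Binomial}(2, m/4)$, i.e. probabilities
$((1-q)^2,\, 2q(1-q),\, q^2)$ with $q = m/4$. The binomial link preserves
the conditional mean round by round, so both the mean and the OLS slope are
recovered without bias; the intercepts work out to 1.520, 0.891 and 2.124,
keeping $m_k(r) \in (0.6, 3.7)$, so clipping to the menu range never binds
under the defaults.

Questionnaire behaviour is generated with per-type yes-probabilities. Only
one of these is anchored by a published number — the pooled Q5 yes-rate of
about 0.606 — so the Q5 entries are 0.61 (prosocial) and 0.60 (free rider),
which pool to 0.575 × 0.61 + 0.425 × 0.60 ≈ 0.606 under the default
mixture. The Q1–Q4 entries (prosocial 0.80/0.30/0.30/0.85, free riders
0.40/0.65/0.65/0.35) are free generator constants chosen to reproduce the
qualitative majority pattern — prosocial types answer yes-Q1, no-Q2, no-Q3,
yes-Q4 — and are exposed in `default_type_params()` for sensitivity work.

Two deliberate simplifications: types are **unconditional on the game
state** (the published statistics identify association between behaviour
and communication, not a reaction function, so none is invented), and the
same parameters apply in both arms (the published means plausibly pool
arms). Both matter for interpretation — see *Limitations*.

## The synthetic experiment

`simulate_experiment()` reproduces the study design: control sessions with
11/8/8 groups of sizes 3/7/11 (177 players) and treatment sessions with
10/8/8 (174 players). The prosocial (cooperator + altruist) prevalence is
57.5% in treatment and 42.5% in control, read as within-arm proportions
(the arms are nearly equal-sized, so the alternative across-arm reading is
nearly identical); the cooperator:altruist split within the prosocial pool
is 2:1, a generator choice reflecting cooperators being the commonest type.
Both are arguments of `experiment_design()`. All randomness flows from one
seed, and identical seeds give byte-identical datasets.

What the generator does **not** emulate: reaction to deficits or to
majority verdicts, dropouts/timeouts, session and demographic structure,
and the two replication experiments. Consequently success is rarer than in
human data — the unconditional mixture yields expected per-capita
investment of about 1.65 (treatment) and 1.41 (control) units per round,
below the fair share, so medium and large groups usually fail. The
qualitative orderings survive (treatment above control at every size;
success falling with group size), and those are what the test suite
asserts; passing tests validate the machinery and the calibration, not the
absolute success rates of human groups.

## The random-play null

The null against which "giving up" is judged is i.i.d. uniform play over
the menu. The uniform choice is the package's reading of "random-playing
groups": it is symmetric, its per-round mean equals the fair share, and it
makes the null's expected surplus zero at every round, consistent with
envelopes centred on zero. Under it:

* `sum_distribution()` computes the exact distribution of the group's
  cumulative investment by iterated convolution over $n \times R$ draws
  (dynamic programming on the lattice of even sums).
* `success_probability()` is the exact tail $P(S \ge T)$; because the
  uniform draw is symmetric about the fair share, it equals
  $(1 + P(S = T))/2$, a useful closed-form cross-check (agreement to
  1e−12 is asserted).
* `failure_envelope()` simulates groups, conditions on **final** failure
  only (not path-wise), and reports per round the empirical
  $(1-\text{level})$ quantile of surplus — by default the 5th percentile,
  so 95% of unsuccessful random groups stay above the curve. Quantiles use
  the standard linear-interpolation order statistic (R type 7). The default
  is 100,000 replicates with the seed recorded on the result; at that size
  the envelope is stable to a fraction of a capital unit.

`flag_beyond_envelope()` marks rounds where an observed trajectory dips
below the curve — deficits deeper than chance under random play, the
operational meaning of a group having given up.

## Analysis pipeline

**Contingency table and log-linear models.** Each group contributes one
count to the arm × success × size table. All nine hierarchical models for a
three-way table (mutual independence, three joint-independence, three
conditional-independence, homogeneous association, saturated) are fitted by
iterative proportional fitting, with every sufficient margin required to
match the observed margin to 1e−10 (verified post-fit, not assumed). Fit is
summarised by the deviance $G^2 = 2\sum o \ln(o/\hat e)$ over non-empty
cells. Selection takes the most parsimonious model (largest residual df)
whose $G^2$ p-value exceeds 0.05, with AIC relative to saturated
($G^2 - 2\,\mathrm{df}$) reported alongside; the saturated model is always
admissible, so selection cannot fail.

**Two-way ANOVA.** The response is each group's mean per-capita investment
in one round. Type II sums of squares handle the mild imbalance (11 vs 10
small groups); a zero-residual (degenerate) fit and underfilled cells are
errors, not silent output.

**Clustering.** Players are clustered on their raw 10-round investment
vectors with Euclidean distance and Ward linkage, the tree cut at $k = 3$,
and clusters labelled by ascending mean investment (lowest → free rider,
middle → cooperator, highest → altruist). The labelling is invariant to
player order and to the arbitrary cluster ids. Raw vectors are used because
the exact engineered features of the original analysis are not published;
distance and linkage are arguments in spirit — the assignment object
carries the tree, so any other cut is a one-liner.

**Trends and ANCOVA.** Per type: the population mean with a
normal-approximation CI over player-round observations, and the OLS slope
of investment on round with its profile CI. The covariance analysis is the
sequential (nested-model) decomposition of `investment ~ type * round`,
giving F statistics for type, round and their interaction; it is checked
against an explicit residual-sum-of-squares oracle in the tests.

**Multinomial choice model.** The per-round choice is modelled by a
multinomial logit with the fair share (2) as reference; default covariates
are round centred at 5.5, arm as an indicator, and size as a categorical
factor (the original specification is not published; this is the package's
coding). Perfect prediction (separation) is detected — a missing outcome
category or exploding standard errors — and reported as an error advising a
regularised refit rather than returning unstable estimates.

**Q5 exact test.** With the loss probability known to be ½, unbiased risk
perception predicts half the Q5 answers positive. The exact upper binomial
tail is computed at the observed count. The published 60.6% yes-rate is
anchored to a reconstructed denominator of 870 = 174 treatment players × 5
scheduled rounds — the true denominator is not printed and may pool
replications — and at that reconstruction the tail probability is below
1e−6, consistent with the published bound.

**MCA.** Q1–Q4 answers (Q5 excluded by design: late appearance, different
nature) are one-hot expanded into an indicator matrix — rows are
player-rounds by default; a per-player modal aggregation is available, with
ties resolved to "no" and flagged. The solution is correspondence analysis
of the indicator: standardized residuals
$S = D_r^{-1/2}(P - rc^\top)D_c^{-1/2}$ decomposed by SVD, principal
inertias the squared singular values, principal coordinates mass-rescaled
singular vectors times singular values. Two exact identities serve as
built-in verification for complete binary data: total inertia equals
$J/Q - 1 = 1$, and four independent balanced questions give four equal
non-trivial inertias of $1/Q = 1/4$. The indicator (not Burt) variant is
the default because those identities hold exactly for it; the Benzécri
inertia re-scaling is available but off by default. `category_map()`
overlays type centroids on the first two dimensions, the representation
behind "prosocial types share optimism and demand action".

## Numerical choices and degenerate inputs

* IPF margin tolerance 1e−10 (relative to table total), iteration cap 200;
  non-convergence is an error carrying the offending margin.
* SVD inertias below 1e−12 are treated as trivial; an all-identical-rows
  indicator yields zero non-trivial inertia with a warning.
* Quantiles are type-7 order statistics; envelope conditioning is on
  final-round failure only.
* Menu clipping of the linear predictor is inert under the defaults but
  enforced for non-default parameters.
* Every stochastic function takes a seed (or inherits the session RNG);
  seeded calls save and restore RNG state, so they do not perturb the
  caller's stream.

## Problem sizes in the shipped checks

The test suite validates parameter recovery with 5,000 simulated players
per type, exact-vs-Monte-Carlo null agreement with 10⁶ replicates per group
size, payout bounds over 10⁵ settlements, and design-level properties
(success-frequency ordering, modal log-linear selection) over 200 replicate
synthetic experiments; the acceptance script uses 20,000 players per type.
These sizes put Monte-Carlo error well inside the tolerances they are
checked against.

## Limitations

* Agents do not react to the game state or to communication content; the
  generator reproduces the published marginal moments and association
  patterns, not strategic feedback. Absolute success rates are therefore
  well below human ones, and analyses whose power depends on real-data
  effect sizes (per-experiment log-linear selection, the arm effect in the
  ANOVA) behave differently on synthetic data than on the original data.
* The three types overlap substantially in 10-round trajectories at the
  calibrated parameters, which bounds what any clustering of raw
  trajectories can recover; the clustering is validated on separated
  archetypes exactly and on synthetic mixtures statistically.
* The Q1–Q4 yes-probabilities and the cooperator:altruist split are
  generator conventions, not published quantities; conclusions that depend
  on them should be checked across `experiment_design()` settings.
* Real experiment data (available from the study's public repository) can
  be loaded through `read_gameplay()`/`read_questionnaire()` and analysed
  with the same pipeline, but no attempt is made to reproduce the original
  figure-level numbers here.
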