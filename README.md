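# crdgame

Simulation and analysis of collective-risk social dilemmas: threshold
public-goods games of the kind used to study cooperation under the threat of
runaway climate change.

## The problem

A group of *n* players (3, 7 or 11) each starts with an endowment of 40
capital units and plays 10 rounds. In each round every player invests 0, 2
or 4 units into a common pool. If the pool reaches the target

> T = 2 × 10 × n (60, 140 or 220 units),

every player converts retained savings into money (¥2 per unit, plus a ¥15
show-up fee, so payouts span ¥15–¥95). If the target is missed, all savings
are wiped with probability ½. Investing the *fair share* of 2 units every
round exactly reaches the target, so the per-round group surplus

> s(r) = Σ investments up to round r − 2·n·r

tracks whether a group is on course. In the *treatment* arm, players
additionally answer up to five anonymous yes/no sentiment-and-outlook
questions between rounds (Q1–Q2 every round, Q3–Q4 from round 2, Q5 from
round 6) and see only the group majority's answers; *control* groups play in
silence.

The package provides, for researchers in experimental/behavioural game
theory:

* **exact game mechanics** — configuration, feasibility, surplus accounting,
  settlement with the loss lottery (`game_config()`, `surplus_series()`,
  `settle()`);
* **behavioural-type agents** — cooperators, free riders and altruists with
  expected per-round investment a + b·r calibrated so that the population
  means are 1.96 / 0.77 / 2.96 units and the slopes 0.080 / −0.022 / 0.152
  units·round⁻¹; draws are 2·Binomial(2, m/4), which preserves the mean
  exactly (`default_type_params()`, `sample_investment()`);
* **a synthetic experiment generator** matching the study design (control
  11/8/8 and treatment 10/8/8 groups of sizes 3/7/11; prosocial prevalence
  57.5% vs 42.5%) (`simulate_experiment()`);
* **the random-play null model** — exact success probabilities by dynamic
  programming and Monte-Carlo significance envelopes for unsuccessful groups
  (`sum_distribution()`, `success_probability()`, `failure_envelope()`);
* **the analysis pipeline** — arm × success × size contingency tables with
  all nine hierarchical log-linear models fitted by iterative proportional
  fitting, two-way ANOVA of per-capita investment, Ward clustering into
  behavioural types, per-type trend/ANCOVA estimates, multinomial
  investment-choice models, the exact Q5 binomial test, and multiple
  correspondence analysis of the questionnaire (`success_table()`,
  `fit_loglinear()`, `cluster_players()`, `type_trends()`, `fit_mca()`,
  `crd_report()`).

Everything takes and returns tidy data frames, has `tidy()`/`glance()`
methods, and `autoplot()` figures.

## Worked example

```r
library(crdgame)

ex <- simulate_experiment(seed = 1)
ex
#> <crd_experiment>
#>   53 groups, 351 players, 3510 gameplay rows, 7482 answers
#>   control success rate: 0.04
#>   treatment success rate: 0.12

report <- crd_report(ex)
tidy(report$trends)
#>   type       n_players  mean mean_low mean_high   slope slope_low slope_high
#> 1 altruist          46 2.91     2.79      3.03   0.100     0.0588     0.142
#> 2 cooperator       117 2.00     1.92      2.09   0.0899    0.0607     0.119
#> 3 free_rider       188 0.766    0.715     0.817 -0.0355   -0.0531    -0.0178
```

The clustered types recover the generative calibration: cooperators average
about 2 units per round with a small positive trend, free riders about 0.77
with a flat-to-negative trend, and altruists about 2.9 with the steepest
increase. The success rates show communication helping (0.12 vs 0.04 here),
though the unconditional generative agents produce far fewer successes than
human groups, whose members react to mounting deficits.

```r
glance(fit_loglinear(success_table(ex$gameplay), "cond_arm.size_given_success"))
#>   model                          g2    df p.value   aic
#> 1 cond_arm.size_given_success  4.92     4   0.295 -3.08

success_probability(3)          # exact P(random play reaches 60)
#> [1] 0.5443245

report$q5
#>   yes_count     n proportion      p_value
#> 1       520   870      0.598 4.53e-09
```

The conditional-independence model (arm × success and size × success terms)
fits this table adequately; `select_loglinear()` ranks all nine models by
parsimony. The Q5 test shows the pooled yes-rate on the risk-perception
question sits far above the 50% that unbiased risk perception would imply.

## Documentation

The methods vignette (`vignettes/collective-risk-dilemma.Rmd`) describes the
game mechanics, the generative behavioural model and its calibration, the
null model and envelopes, every analysis stage, and the package's numerical
and design choices, including what the synthetic generator does and does not
emulate about human play.
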