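# crdelegate

Simulation and analysis of **delegated collective-risk dilemmas** (CRDs):
threshold public-goods experiments in which participants either choose their
contributions round by round, or program an *artificial delegate* — a small
conditional algorithm — that contributes on their behalf for the whole game.

The package is aimed at behavioral and computational social scientists who
want to (i) replay and probe the delegate algorithm used in such
experiments, (ii) generate synthetic study datasets with a realistic
behavioral structure, and (iii) run the full analysis layer — group and
individual metrics, behavioral clustering, factorial statistics — on either
synthetic or deposited experimental data.

## The game and the delegate algorithm

A group of `n = 4` players starts with an endowment of `E = 40` ECoins
each. Over `R = 10` rounds every player contributes an amount from the
treatment's action space (`{0, 2, 4}` with 3 choices, `{0, 1, 2, 3, 4}`
with 5). The group succeeds when the public account reaches the threshold
`T = 80`:

```
success  ⇔  Σ_r Σ_i c_{r,i} ≥ T
payoff_i =  E − Σ_r c_{r,i}          if success, or failure without loss
payoff_i =  0                        if failure and the group-level
                                     Bernoulli(p = 0.5) loss event fires
```

The fair share is `T / n = 20` ECoins per player, i.e. 2 per round.

A delegate is programmed as a **strategy table**: a starting action `a₀`;
a first reaction table `S₁: A → A` mapping the *rounded average* of the
other members' previous-round contributions to an action; a switch value
`w ∈ [0, 120]`; and a second table `S₂`. Round 1 plays `a₀`; from round 2
the agent plays `S₁(⌊x̄₋ᵢ⌉)` until the public account at a round boundary
reaches `w`, after which it plays `S₂(⌊x̄₋ᵢ⌉)` for the rest of the game
(the switch never reverts). Rounding ties break toward the larger action.

The analysis layer clusters the 10-round action vectors with k-means
(Lloyd, raw vectors, pooled over both games), selects k by an elbow rule on
the inertia curve, names clusters as *early / high / fair / low*
contributors, and compares treatments with Welch's one-sided t test,
Fisher's exact test and a two-way factorial ANOVA with interaction
(Type II sums of squares by default).

## Worked example

Simulate the full 2×2 study (choices × delegation, 30 groups of 4 per
cell, two consecutive games with outcome-dependent revision in between)
and analyse it:

```r
library(crdelegate)
library(dplyr)

study <- generate_study(study_design(n_groups = 30, seed = 2024))

group_metrics(study) |>
  group_by(game, treatment_choices, treatment_delegation) |>
  summarise(mean_pa = mean(final_public_account), success = mean(success),
            mean_var = mean(private_account_variance), .groups = "drop")
#>   game treatment_choices treatment_delegation mean_pa success mean_var
#> 1    1                 3                FALSE    75.6   0.533     44.9
#> 2    1                 3                 TRUE     90.5   0.733    138.3
#> 3    1                 5                FALSE    82.5   0.767     15.9
#> 4    1                 5                 TRUE     90.9   0.733     43.5
#> ...
```

Delegation cells overshoot the 80-ECoin target on average and show several
times more within-group inequality (`mean_var`, the variance of members'
final private accounts) than no-delegation cells — the generator's default
population is calibrated to reproduce exactly these qualitative contrasts.
The treatment tests and the behavioral profiling:

```r
study_tests(study) |>
  filter(game == 1, test_name == "welch_t")
#>                                 contrast statistic   df p_value
#> 1 delegation - no-delegation | 3 choices      2.33 43.0  0.0124
#> 2 delegation - no-delegation | 5 choices      1.67 37.4  0.0516

labels <- label_behaviors(study, k = 4, seed = 2024)
round(100 * prop.table(table(labels$treatment_delegation, labels$behavior), 1), 1)
#>         early fair high  low
#>   FALSE  35.2 44.2  6.2 14.4
#>   TRUE    7.7 47.9 33.1 11.2
```

Under 3 choices, delegation groups contribute significantly more
(one-sided Welch t = 2.33, p = 0.012); early contributors dominate only
when people play by themselves, while delegates are far more often
programmed as high contributors. `plot_public_accounts()`,
`plot_private_variance()`, `plot_success_rates()` and
`autoplot()` on a `cluster_actions()` result draw the standard figures,
and `inst/cli/crd.R` exposes `simulate` / `analyze` subcommands for shell
use. `read_study()` ingests external long-format CSVs through a
column-mapping adapter with full invariant validation.

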