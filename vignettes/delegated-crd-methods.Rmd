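---
title: "Models and methods behind crdelegate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crdelegate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crdelegate)
```

This vignette documents the models implemented in `crdelegate`, the
assumptions behind them, the parameters a user may want to tune, and the
design decisions taken where more than one reasonable formalization
existed.

## The collective-risk dilemma engine

The collective-risk dilemma (CRD) is a threshold public-goods game with a
delayed, risky payoff. The engine (`crd_config()`, `play_game()`,
`resolve_outcome()`) fixes the study conditions as defaults: groups of 4,
10 rounds, endowment 40 ECoins, threshold 80, risk 0.5, and one of two
action spaces — `{0, 2, 4}` (3 choices) or `{0, 1, 2, 3, 4}` (5 choices).
All currency is integer-valued; the configuration constructor enforces
`max(action_space) × rounds ≤ endowment`, so overdrawing is structurally
impossible.

Decisions worth making explicit:

* **Inclusive threshold.** Landing exactly on 80 counts as success: the
  collective target is a sum to be *reached*, and four fair-share players
  (2 ECoins × 10 rounds × 4 players) must succeed exactly.
* **One loss draw per group.** The risky loss on failure is a group-level
  gamble: a single Bernoulli(risk) draw shared by all members, not an
  independent draw per player. Consequently all members of a failed group
  either keep their remaining endowments together or lose them together.
* **Simultaneous moves.** Within a round every policy observes the same
  pre-round public account; nobody sees a co-player's current-round
  choice. Round 1 has no history, so policies receive an explicit `NA`
  sentinel for the others' previous-round average and must not rely on it.
* **Inequality is measured pre-risk.** `group_metrics()` computes the
  within-group variance of *pre-risk* private accounts
  (endowment − own total contribution, sample `n − 1` denominator), so the
  measure captures contribution asymmetry and is not contaminated by the
  shared gamble; a `post_risk = TRUE` option exists for sensitivity
  analysis.

## Delegate semantics

A delegate program (`strategy_table()`) is a starting action, two total
reaction tables over the action space, and a public-account switch value
in `[0, 120]`. The semantics implemented by `delegate_policy()`:

* The reaction key is the mean of the *other three* members'
  previous-round contributions, snapped to the action space by
  `round_to_space()`. Exact ties (averages 1.0 and 3.0 in the 3-choice
  space) break **toward the larger action**; since the direction is not
  dictated by the problem, a `tie_rule = "down"` flag allows flipping the
  rule when checking sensitivity on external data.
* The switch is evaluated at round boundaries, before actions are chosen,
  against the public account accumulated through the previous round, with
  `≥` comparison. Because the public account never decreases, "has the
  account ever reached the switch value" is equivalent to "has it reached
  it now", which makes the policy a pure function of the observable round
  state — and the switch automatically irreversible.
* `classify_table()` calls a program *strategy-1 constant* when its first
  reaction table is a single repeated action, and *fully constant* when
  both tables and the starting action all equal that action — only then is
  the realized behavior literally fixed regardless of the group.

The delegate semantics are verified in the test suite against an
independent brute-force interpreter over all 3⁷ = 2,187 3-choice programs
at a fixed mid-game switch, plus randomized 5-choice programs.

## The synthetic population generator

`generate_study()` emulates the statistical structure the analysis layer
assumes, not human psychology. Its building blocks:

**Behavioral profiles.** Four latent per-round target sequences: *fair*
(2 every round), *high* (3.4), *low* (0.8), *early* (4 in rounds 1–5, 0 in
rounds 6–10). The off-center values 3.4 and 0.8 are chosen so the snapped
behavior lands on the intended side of the fair share in *both* action
spaces: 3.4 → 4 under 3 choices and 3 under 5; 0.8 → 0 under 3 choices but
1 under 5, which reproduces the observation that a finer action grid lets
selfish players contribute *something* rather than nothing. Realized
actions are `round_to_space(target + ε)` with ε ~ N(0, `noise_sd`²),
truncated to the action range; the default `noise_sd = 0.25` keeps most
rounds at the profile's modal action with occasional one-step deviations,
which we consider realistic within-profile variability for a 10-round
game.

**Treatment mixtures.** Only the fair-contributor shares are empirically
anchored (3 choices: 46% delegation / 57% no-delegation; 5 choices: 47% /
40%). The remaining mass per cell is a free parameter fixed once to
reproduce the observed qualitative ordering — delegation cells hold more
high and low contributors and few early contributors; no-delegation cells
many early contributors and almost no high contributors; fewer low
contributors under 5 choices than under 3 (see `default_mixtures()`).
These choices were made a priori from the ordering constraints, not fitted
to any statistic.

**Delegate programs.** `sample_strategy_table()` builds reaction-table
entries as `round_to_space(base + w·(x − 2))`, anchoring the entry at the
fair key `x = 2` to the profile's phase mean (`base`), with reciprocity
slope `w ∈ {0.5, 1}`. With probability `1 − p_conditional` (default
`p_conditional = 0.9`, mirroring the observation that most programs are
conditional) the table is instead constant and truly fixed. Front-loaded
(early) profiles receive a switch value in 41–50 — which against
fair-share opponents fires exactly at the round-6 boundary — and a
strategy 2 built from the low second-phase targets, so the early→low drop
is implemented through the switch, as the delegate formalism intends.
Flat profiles receive a switch in 81–120, mostly immaterial before the
target is reached.

**Between-game revision.** The experimental finding fixes only signs:
delegating members of failed groups increase their contributions;
successful delegation groups that overshot correct downward; failed
no-delegation groups skew much lower. `revision_params()` therefore
exposes three free magnitudes with documented defaults chosen once:
`delta_up = 1` ECoin/round (a one-notch upward shift of the latent
targets, rebuilt into the same program structure), `delta_down = 0.5` on
overshoot, and `p_giveup = 0.6` (the probability that a failed
no-delegation member abandons the public good and becomes a zero
contributor). Revision acts on latent targets, never on realized
sequences, so Game 2 remains policy-generated.

**What the generator does not emulate.** Individual heterogeneity within
a profile beyond Gaussian jitter; learning within a game; any dependence
of programming on the comprehension or attitudes of participants; and the
empirical *levels* of success rates or public-account means — only the
directions of the treatment contrasts are calibrated. Passing tests
therefore demonstrate that the analysis layer recovers the structure the
generator plants, under the stated noise; they are not evidence about
human behavior.

**Randomness.** All randomness flows from one master seed:
`generate_study()` derives one integer substream seed per group, and each
group splits it further into fixed slots (profile draw, member creation,
per-game noise, revision, per-game risk draws). Identical designs are
byte-identical; distinct groups are independent.

## Behavioral clustering

`cluster_actions()` runs Lloyd k-means on the raw 10-element action
vectors (Euclidean distance, best of `n_init = 10` restarts). No
standardization: all coordinates share units, and scaling would distort
the fair-share anchor at 2. Game 1 and Game 2 vectors are pooled before
clustering; by default the two choice conditions are clustered separately
(`label_behaviors(by_choices = TRUE)`), since the treatments live on
different action grids, with a pooled mode available.

**Elbow rule.** `select_k_elbow()` computes the inertia curve over
`k_range` and formalizes the visual elbow as the **maximum second
difference of log-inertia**. The rationale: while genuine clusters are
being separated, inertia decays roughly geometrically; past the true
number of clusters it plateaus at the noise floor; the log-curvature
maximum sits exactly at that transition. A raw (linear) second difference
is dominated by the always-large absolute drop away from k = 1 and — as a
closed-form check on four noiseless profile archetypes shows (inertia
5512.5, 2667, 1000, 0 for k = 1…4 at 50 copies each) — would place the
elbow at k = 2 even when a perfect 4-cluster structure exists. The log
rule selects k = 4 on noiseless archetypes, on noisy synthetic
populations at noise sd up to 0.5, and on full default studies in both
choice conditions (validated over 20 geometry × seed combinations before
freezing the rule). Degenerate inputs short-circuit: if some k attains
numerically zero inertia, the smallest such k is returned.

**Naming.** `name_clusters()` applies the verbal profile definitions to
each centroid: *early* if the first-half mean exceeds 2, the second-half
mean is below 2, and their difference exceeds δ = 1; otherwise *high* /
*low* if the overall mean is above 2 + ε / below 2 − ε with ε = 0.5, and
*fair* in the band around 2. δ and ε are free parameters whose defaults
make the verbal definitions literal; duplicate names across centroids are
permitted but flagged.

## Statistical suite

* `welch_t()` — unequal-variance t with Welch–Satterthwaite degrees of
  freedom (via `stats::t.test`), one-sided where the hypothesis is
  directional. Chosen because the treatment cells are strongly
  heteroskedastic.
* `fisher_exact()` — exact hypergeometric inference on 2×2 tables (via
  `stats::fisher.test`), two-sided by default with one-sided flags; the
  sidedness is a documented choice since it is not dictated by the
  design.
* `anova_two_way()` — factorial ANOVA with interaction on possibly
  unbalanced cells, Type II sums of squares by default (each main effect
  adjusted for the other, the interaction for both; `car::Anova`);
  Type III, with sum contrasts, by flag. Type II is the conventional
  default absent a priori interaction-focused contrasts; results on
  unbalanced data are sensitive to this choice, which is why it is
  exposed.
* No multiple-testing correction is applied anywhere, matching the
  reporting style of the experiments this pipeline targets.

All three are verified against independent oracles in the test suite:
the textbook Welch formula, full enumeration of hypergeometric table
probabilities, and closed-form balanced-design sums of squares, plus a
10,000-replicate null simulation of the one-sided Welch type-I error.

## Problem sizes and determinism

The test suite runs every component at the scale it is used: full 2×2
studies at 30 groups per cell across 20 replicate seeds for the
qualitative treatment contrasts, 10,000 Monte-Carlo draws for the risk
resolution and the type-I error, the exhaustive 2,187-program delegate
sweep, and 200-vector clustering-recovery populations. These sizes give
sampling errors comfortably below the margins being asserted while
keeping a full run around two minutes. Every stochastic test and the
acceptance script fix their seeds explicitly; `play_game()` itself is
deterministic apart from the single loss draw.

## Known limitations

* The generator's revision magnitudes and mixture remainders are sign
  -calibrated free parameters; empirical levels (e.g. cell success
  rates) are not targets and will not match any particular experiment.
* The elbow rule assumes an inertia curve with a single
  geometric-to-flat transition; heavily overlapping cluster structures
  at high noise can still yield an ambiguous k (3 vs 4).
* `read_study()` validates structure and recomputes derivable fields,
  but it cannot detect semantically wrong but internally consistent
  inputs (e.g. relabeled treatments).
* The engine models no continuous action spaces, heterogeneous
  endowments, within-game learning, or mid-round sequential information.
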