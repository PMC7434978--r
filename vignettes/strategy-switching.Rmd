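---
title: "Detecting strategy switches in sequential foraging choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting strategy switches in sequential foraging choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeswitch)
```

## The scientific problem

A bee trained to find sucrose on the larger (or smaller) of two shapes can
pass a discrimination test in more than one way. It may have learned the
relational rule, or it may exploit a much cheaper heuristic: win-stay /
lose-switch (WSLS), i.e. repeat the stimulus class that just paid off and
abandon the one that did not. Overall accuracy cannot separate the two,
because both strategies raise it. The separation lives in the *within-bout
choice sequence*:

- a rule user is accurate from the very first landing of a bout;
- a WSLS user's first landing is uninformed (there is no previous outcome),
  but its second landing is steered by the first outcome.

`beeswitch` packages this logic: block-wise accuracies computed separately
from all, first and second choices; the two outcome-conditioned
probabilities with their *enumerated* chance levels; a stopped Markov-chain
model of bout performance; exact nonparametric tests; and an agent-based
generator that produces choice logs with known ground truth.

## The arena and its chance levels

The arena is a 3 x 2 grid of six 7-cm discs (centres 14 cm apart
horizontally, 9.3 cm vertically), three carrying the rewarded size class
and three the punished one. Two structural features shape every statistic:

1. **No immediate revisit.** A bee never lands twice in a row on the same
   disc, so a second choice samples 5 discs, not 6.
2. **Depletion.** Each rewarded disc pays out once per bout; a bout ends
   when all three rewards are collected.

An uninformed first choice is therefore correct with probability
$r/n = 1/2$, while an uninformed *second* choice is correct with
probability $(r-1)/(n-1) = 0.4$ after a correct first landing and
$r/(n-1) = 0.6$ after an incorrect one. `chance_level()` implements these
closed forms for any $0 < r < n$; the test suite verifies them against an
exhaustive enumeration over all rewarded-set assignments and ordered disc
pairs for $2 \le n \le 8$. All inference functions take the chance level
as an argument rather than hard-coding 0.4/0.5/0.6, so a different arena
composition flows through automatically.

These conditional chance levels are exact for *second* choices. For third
and later choices they are an approximation: depletion removes rewarded
discs' payouts (though not their stimulus class) and revisits of
non-adjacent discs are allowed, so the composition of "informative" discs
drifts as a bout progresses. The package follows the convention of
applying the 0.4/0.6 benchmarks to the second choice only; longer chains
are handled by the Markov model, not by chance-level comparisons.

## Conditional probabilities and the total-probability identity

For bouts with at least two landings, each bee's win-stay and lose-switch
probabilities are estimated as empirical joint over marginal frequencies,

$$\hat p_{ws} = \frac{\#\{c_1 = 1, c_2 = 1\}}{\#\{c_1 = 1\}}, \qquad
  \hat p_{ls} = \frac{\#\{c_1 = 0, c_2 = 1\}}{\#\{c_1 = 0\}},$$

then averaged across bees (per-bee-first aggregation; a pooled-count
variant is available by pooling the returned counts). An empty
conditioning margin — a bee that was never wrong on its first choices in a
block — propagates as *undefined*, never as zero, and is excluded from the
cross-bee mean with a warning.

By construction the estimates satisfy, per bee and exactly,

$$P\{c_1=1\}\,\hat p_{ws} + P\{c_1=0\}\,\hat p_{ls} = \text{second-choice
accuracy},$$

which the acceptance tests check to $10^{-12}$ on simulated data of every
strategy. Whether the conditioning event is the first choice's
*correctness* (default) or its *reward outcome* is a flag
(`condition_on`), since the two differ once depletion makes correct
landings unrewarded.

## The stopped Markov-chain model of bout performance

The model describes one bout as a two-state chain on landing outcomes:
the first landing is correct with probability $P\{c_1\}$, and every later
landing is correct with probability $p$ (previous landing correct) or $q$
(previous incorrect), with homogeneity — all later transitions borrow the
second-given-first conditionals. The bout stops in success once
`rewards_needed = 3` correct outcomes accrue, or in failure at error
number `max_errors + 1 = 3`; completed sequences therefore carry at most
two errors and have length 3–5, matching late-training bout lengths of
about five landings. `max_errors` is configurable for sensitivity
analyses.

Two readings of the stopping rule are possible (stop *at* the
`max_errors`-th error, or tolerate `max_errors` errors and stop at the
next one). We implement the second: it is the one under which the maximum
sequence length equals `rewards_needed + max_errors`, the degenerate rule
(1, 0) collapses to $\text{Perf} = P\{c_1\}$ exactly, and completed
successful bouts carry "two, one or no" errors.

Performance is the expectation of the *fraction* of correct landings,
$\text{Perf} = \sum_s P(s)\, \tfrac{\#C(s)}{|s|}$, computed by exhaustive
enumeration of the 20 admissible sequences (probabilities must sum to 1
within $10^{-12}$); the expected *count* of correct landings is also
returned, since either weighting is defensible and the choice matters at
the third decimal. An independent vectorised Monte-Carlo sampler
(`simulate_markov_bouts()`) serves as an oracle: the acceptance suite
checks enumeration against $10^6$ sampled bouts on a $5^3$ parameter grid.

**Known limitation.** The homogeneity assumption is structurally violated
by the generator's own WSLS agents: their memory keys on *reward*, and
once a rewarding disc is drained a correct landing reads as a loss and
pushes the agent off the correct class. Later transitions are therefore
poorer than the second-given-first conditionals, and the chain
over-predicts whole-bout accuracy for WSLS cohorts — visible in
`analysis/03_markov_model.R` as a positive predicted-minus-observed gap in
the WSLS block. The paired comparison machinery itself is validated by a
self-consistency test in which the fitted chain generates the
observations, where it rejects at the nominal rate. For the same reason
the package makes no claim that the model-fit test alone dates the
switch; the block-evidence analysis below does that.

## Exact nonparametric inference

Sample sizes here are small (18 bees), so the inference layer is exact:

- **Signed-rank test** (`signed_rank_test()`): zero differences dropped,
  mean ranks for tied magnitudes, and the null distribution of the
  positive-rank sum enumerated over all $2^n$ sign assignments via dynamic
  programming on doubled ranks (exact up to `exact_max = 20`, i.e. always
  at study scale). Above that, a tie-corrected normal approximation with
  continuity correction takes over; the two paths agree within 0.01 at
  n = 18. The DP is cross-checked in the tests against a brute-force
  enumeration and against `stats::wilcox.test` on tie-free data.
- **Spearman correlation** (`spearman_correlation()`): rho is the Pearson
  correlation of mean ranks; the p-value is the full permutation
  distribution (enumerated in C++ over distinct rank arrangements, which
  is tie-safe) for $n \le 10$, and the t approximation beyond.
- Directional claims (above-chance, split-half improvement) are tested
  one-sided; the model-observed comparison is two-sided. Both sidedness
  and an optional Holm adjustment are caller-controlled; none is applied
  by default.

## Switch detection

Per block of 10 bouts: *rule evidence* = first-choice accuracy above the
unconditioned chance level; *WSLS evidence* = both conditionals above
their enumerated chance levels (all one-sided exact signed-rank tests at
$\alpha = 0.05$). Blocks are labelled `rule`, `wsls`, `mixed`, `random`
or `indeterminate`, and the switch block is the first with WSLS evidence
and no rule evidence, after at least one rule block. The block grid is
deliberately the same one the descriptive analysis uses — no per-bout
changepoint machinery — so the inference mirrors how the data are
summarised. The acceptance suite measures operating characteristics at
study scale: 200 hybrid cohorts (18 agents, switch at bout 21) must yield
the true switch block in at least 90% of runs, and 200 pure-rule cohorts
must produce false switches in at most 10%.

## The synthetic generator

`simulate_cohort()` emulates the study conditions: 18 bees split 10/8
across the two reward contingencies, 30 training bouts, per-bout stimulus
draws from the printed catalogue (one shape, one colour, two of three
sizes; star and yellow reserved for the transfer tests), depletion, a
20-landing safety cap, and three unrewarded tests of 10 landings each
(standing in for the 120-s window, length configurable) separated by two
refresh bouts. Reproducibility is bit-for-bit from one master seed, with
per-bee child seeds drawn deterministically.

Agent parameters, all configurable via `agent_spec()`:

| parameter | default | role |
|---|---|---|
| `rule_accuracy_min/max` | 0.5 / 0.75 | floor and ceiling of the rule ramp |
| `rule_learning_rate` | 0.15 /bout | $p(b) = p_{min} + (p_{max}-p_{min})(1-e^{-\lambda b})$ |
| `wsls_fidelity` | 0.4666 | probability a WSLS choice follows the heuristic |
| `switch_bout` | — | first WSLS bout of a hybrid agent |
| `test_revert_after` | 5 choices | unrewarded landings before a hybrid falls back on its rule |

The ramp ceiling of 0.75 puts mid-training first-choice accuracy in the
low-70s (per cent), the level at which the first-choice signature is
clear but imperfect. The WSLS fidelity default is set so that the agent's
expected second-choice accuracy, $(1+f)/2$ on this arena, lands at the
~73% level characteristic of late training in this paradigm, implying
win-stay ≈ 0.68 and lose-switch ≈ 0.79. In unrewarded tests every landing
is a "loss", so a pure WSLS agent keeps switching (uninformative,
accuracy ≈ 1/2); hybrid agents revert to their learned rule after
`test_revert_after` landings, which is what makes the split-half analysis
come out positive.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data:

- *Between-bee heterogeneity.* All agents in a cohort share parameters, so
  the training–test correlation is near zero in simulation; the analysis
  is wired and tested for correctness, not for reproducing any particular
  correlation strength. Real cohorts vary in learning ability, which is
  what makes that correlation informative.
- *Efficiency along the hybrid trajectory.* At the default fidelity, WSLS
  bouts average more landings than learned-rule bouts, so simulated
  choices/bout do not fall across training as real bees' do; the
  efficiency comparison that does hold (and is tested) is WSLS versus an
  uninformed random searcher.
- No visual processing, flight kinematics, motivation or satiation
  dynamics; "120 s" is a fixed landing count; quinine aversion is just
  the binary correct/incorrect outcome.

## Numerical and interface conventions

- Coordinates: disc centres on the 3 x 2 grid, x rightward, y upward,
  origin at the bottom-left disc, units cm. Distance ties (present for the
  middle-column discs) take mean ranks, unbiased under the uniform null;
  the "nearest rate" counts untied rank-1 transitions, and the uniform
  null for the default grid is enumerated, not assumed to be 1/5.
- Blocks are $[1..k], [k+1..2k], \dots$ with a trailing partial block
  retained and flagged; 30 bouts divide evenly for both k = 6 and k = 10.
- Undefined statistics (empty denominators) are `NA` and excluded with
  warnings, never silently zero.
- The choice-log CSV dialect is fixed: comma, decimal point, UTF-8,
  `\n`, booleans as 0/1, mandatory header; the reader enforces the schema
  and the `reward implies correct` invariant with line-numbered errors.
- Star area uses a regular-pentagram construction from the printed point
  side length (inner pentagon of side $2s\sin 18°$ plus five apex-36°
  isosceles points); the construction is one reading of the printed
  dimension and is cross-checked in the tests against an independent
  shoelace computation on the polygon outline.

## Validation problem sizes

The shipped tests run the chance-level enumeration over all arenas up to
8 discs; the Markov enumeration against $10^6$-bout Monte Carlo on a
$5\times5\times5$ grid; signed-rank validity over 1,000 null cohorts of
18; switch-detection recovery and false-positive rates over 200 + 200
cohorts of 18 agents; and the full qualitative pattern (chance first
choices, elevated second choices and conditionals, WSLS efficiency vs
random) on single study-scale cohorts. These sizes were chosen to make
Monte-Carlo error small relative to the tested margins.
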