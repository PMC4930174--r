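---
title: "Reputation, networks, and cooperation: model, simulator, and testing pipeline"
author: "rwcoop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reputation, networks, and cooperation: model, simulator, and testing pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwcoop)
```

## The question

A widely held view in the social sciences is that dense social networks
promote cooperation through *reputation*: if word of a defection spreads to
third parties, defecting becomes more costly, so conditional cooperation
should be easier to sustain. `rwcoop` implements the canonical
game-theoretic formalization of this idea — the Raub–Weesie model of
conditional cooperation under network embeddedness — together with an
agent-based simulator of the corresponding laboratory game, a generator of
lab-shaped synthetic datasets, and the statistical pipeline used to test the
model's predictions on group-level data.

The package is aimed at researchers who want to (a) compute the model's
equilibrium thresholds for arbitrary parameterizations, (b) explore the
model's behavior under relaxations it is known to be fragile to (decision
noise, backward-looking learning), and (c) exercise or power a group-level
experimental analysis before collecting data.

## The model

`n` actors sit on a complete network. Each period, an interaction graph is
drawn uniformly at random among all graphs in which every actor has exactly
`m` partners; matched pairs play a simultaneous two-person Prisoner's
Dilemma with payoffs `T > R > P > S` (temptation, reward, punishment,
sucker), and every unmatched relation pays a constant `Q`. Future payoffs
are discounted by `beta` per period — equivalently, the game continues with
probability `beta`. A given relation is matched in a period with
probability

$$\pi = \frac{m}{n-1}.$$

Two information regimes are contrasted:

* **atomized** — actors observe only the outcomes of their own
  interactions (though they see who was matched with whom);
* **embedded** — actors observe the outcomes of *all* interactions: the
  reputation channel.

The focal strategies are *trigger strategies*: cooperate with a partner
until that partner is observed defecting against anyone within one's
information scope, then defect against that partner forever. Mutual trigger
play is a Nash equilibrium exactly when unconditional defection (ALL-D)
does not pay against triggers, which reduces to a threshold on the discount
factor. Against triggers, ALL-C earns
$(mR + (n-1-m)Q)/(1-\beta)$ in either regime. Under embedded information a
deviator exploits its `m` first-period partners once and faces punishment
everywhere afterwards, giving the classical dyadic condition

$$\beta > \frac{T-R}{T-P} =: \beta_{emb},$$

while under atomized information each relation learns of the deviation only
through its own matches — the deviator keeps collecting `T` from relations
that have not yet met it — which tightens the condition to

$$\beta > \frac{T-R}{T-P-(R-P)(1-\pi)} =: \beta_{ato} \ge \beta_{emb},$$

with equality exactly when $\pi = 1$ (everyone meets everyone each
period). `Q` cancels from both conditions. Reputation thus *weakens* the
condition for cooperation; the standard laboratory parameterization
(`T = 60, R = 40, P = 20, S = 0, Q = 30`, `n = 6`, `m = 2`, hence
$\pi = 0.4$) puts the thresholds at $\beta_{emb} = 1/2$ and
$\beta_{ato} = 5/7$:

```{r}
mod <- rw_model()
coef(mod)
predict(mod, beta = c(0.5, 5/7))
```

The theory is evaluated at an infinite horizon even though the emulated
experiment runs 40 periods; this mirrors standard practice (finite-horizon
play resembles infinite-horizon play until near the end), and
`eu_finite_horizon()` is provided purely as a diagnostic — it is *not* an
equilibrium analysis of the finite game. The equilibrium concept is Nash in
trigger strategies; subgame perfection is not examined.

## The matching sampler

The model requires each period's interaction graph to be drawn uniformly —
"each relation with equal probability" — over *all* labeled `m`-regular
graphs on `n` vertices. Greedy edge-by-edge matching does not deliver this,
so `sample_matching()` uses two exact routes:

* for `n <= 8`, all graphs are enumerated once by backtracking (for the
  default `n = 6`, `m = 2` there are exactly 70: 60 labeled 6-cycles and 10
  pairs of triangles), cached, and drawn by uniform index;
* for larger `n`, stub-pairing (configuration-model) rejection sampling is
  used. Conditioning a uniform stub pairing on producing a simple graph is
  *exactly* uniform over simple `m`-regular graphs, because every such
  graph corresponds to the same number, $(m!)^n$, of pairings.

Enumeration is capped at `n = 8` because the number of labeled regular
graphs explodes (about $1.1 \times 10^7$ 3-regular graphs at `n = 10`);
the pairing route loses nothing statistically, only the ability to index
the full support.

## The simulator

`run_group()` plays the exact laboratory game: per-period uniform matching,
strictly simultaneous decisions based on information through the previous
period, cumulative never-forgotten observations scoped by the information
regime, stage payoffs from the realized actions. Strategies
(`strategy_spec()`):

* `TRIGGER`, as defined above. A deliberate design choice is that the
  trigger is *non-discriminating*: any observed defection by `j` triggers
  against `j`, including `j`'s own retaliation. The strategy definition's
  "any defection" reading is also the one under which the noise-cascade
  argument below goes through. A `discriminating = TRUE` variant (ignore
  defections that are retaliation against a defection the defector had
  itself observed) is provided to explore the conjecture that subjects
  forgive retaliation; it is off by default.
* `STRONG_TRIGGER`: defect against everyone after any observed defection
  by anyone.
* `ALL_C`, `ALL_D`: unconditional play.
* `LEARNING`: the literature invoked by the noise/learning alternative
  explanations names no equations, so the package implements the simplest
  standard backward-looking model: Bush–Mosteller aspiration reinforcement,
  per directed dyad. The cooperation propensity starts at `init` (default
  0.5) and moves by `rate * s` toward (away from) the action just played,
  where the stimulus `s` is the realized payoff's distance from the
  aspiration level, normalized to `[-1, 1]`; the aspiration is expressed as
  a fraction of the payoff range (default 0.5, i.e. 30 points). This is
  explicitly an interpretation, and all three parameters are configuration
  surfaces, not calibrated claims.

Every decision is independently flipped with probability `tremble`
(symmetric implementation noise; the model's own world is `tremble = 0`).
Intended and realized actions are both recorded, so analyses can condition
on error events. A forced defection can be injected into a stated
dyad-period (`inject =`), which is how the package encodes the model's key
fragility as a reproducible trace:

```{r}
rec <- run_group(group_config(condition = "embedded"),
                 strategies = strategy_spec("TRIGGER"), seed = 42,
                 inject = list(period = 1, actor = 1))
round(cooperation_trajectory(rec), 3)[1:10]
```

One accidental-looking defection under embedded information triggers
retaliation, the retaliation is itself observed by everyone, and the group
cascades to universal defection; the same injection under atomized
information stays locked inside the one affected dyad forever. This is the
noise argument against the reputation prediction: with trembles, embedding
produces *less* cooperation on average, or at least more across-group
variance.

## The synthetic-data generator

No raw data from the motivating experiments are publicly deposited, so the
analysis stage is developed and validated against synthetic datasets shaped
exactly like the lab's: one row per matched dyad-period, with experiment,
group, condition, period, the two actors, their realized actions, and their
stage payoffs. `experiment_design()` fixes the study conditions:

* preset `"exp1"`: 7 atomized + 7 embedded groups; preset `"exp2"`: 6 + 6;
* 6-person groups, 2 partners per period, 40 scored periods (the five
  practice periods of the lab protocol are not modeled — only scored
  periods are ever analyzed);
* a per-actor strategy draw from a `strategy_mixture()`. The lab
  population's true composition is unknown; mixtures are scenario inputs,
  never estimates of it.
* an *endgame ramp*: an extra one-way probability that a realized
  cooperation becomes a defection, rising linearly from 0 at period 36 to
  `endgame_max` (default 0.3) at period 40. Humans defect increasingly in
  the last rounds of a finitely repeated game; the package's strategies
  have no horizon knowledge (and tests verify no endgame decline arises
  endogenously), so this labeled device superimposes the phenomenon for
  pipeline realism. It touches only the last five periods — exactly the
  ones the main analysis window excludes — and is disabled in all
  theory-facing tests.

Group-level seeds are derived from the design seed and the group's
condition-and-index key, so enlarging a design reproduces the existing
groups unchanged. Datasets round-trip exactly through plain CSV
(`write_dataset()` / `read_dataset()`), with the lab's ORANGE/BLUE action
labels accepted and normalized on read, and structural validation (complete
periods, `m`-regular dyad counts per period, one condition per group) with
diagnostics naming group, period, and actor.

What passing tests on these data do and do not show: the generator
reproduces every *structural* property the analysis assumes, and its
behavioral content is whatever the chosen mixture implies. It does not
model session effects, subject demographics, partner choice, or
anonymity differences between sites — conclusions about real lab
populations require real data.

## The statistical pipeline

The unit of analysis is the group. `run_hypothesis_suite()` computes, per
experiment and pooled:

* **H1** — main-window cooperation (default periods 1–35, excluding the
  final five): Mann–Whitney comparison of per-group rates, embedded vs
  atomized.
* **H2** — first-interaction cooperation: for each dyad, only its first
  encounter counts. The action-level rate is the default; a dyad-level
  variant (both-cooperate) is available, since either reading is defensible.
* **Dispersion** — an end-window table (default periods 30–35, inclusive,
  i.e. six periods) of per-condition means and SDs, with a variance
  comparison testing whether embedded groups are more dispersed.

Design choices that were genuinely open, and how they were settled:

* *Mann–Whitney implementation.* For combined `N <= 20` groups the p-value
  is exact: full enumeration of all `choose(N, n_a)` assignments of the
  pooled midranks, so ties are handled by the permutation distribution
  itself; beyond that, the tie-corrected normal approximation with
  continuity correction. Tests cross-check the enumeration against an
  independent pair-counting oracle and, on tie-free inputs, against
  `stats::wilcox.test`.
* *Sidedness.* H1/H2 default to two-sided, the conventional reporting
  choice; `alternative =` overrides. The power analysis defaults to
  one-sided because the reputation hypothesis is directional.
* *Variance comparison.* No specific test is canonical here; the default is
  the F test on the ratio of unbiased sample variances (via
  `stats::var.test`), with a seeded label-permutation variant of the same
  ratio statistic as a robustness option for non-normal rates.
* *Multiplicity.* No correction is applied; all p-values are reported raw,
  matching standard practice for this design.
* *Degenerate inputs.* All-equal rates (e.g. an all-cooperation dataset)
  give p = 1 with a `degenerate` flag rather than an error; a zero-variance
  arm makes the variance comparison degenerate-flagged.

`t_test_power()` computes exact noncentral-t power for the two-sample
t-test (noncentrality $\delta/\sigma\sqrt{n/2}$, `2n - 2` df). At the
benchmark effect size of 0.19 (the cooperation-rate difference
reconstructed from the closest comparable experiment) with SD 0.1 per
group, five groups per arm give

```{r}
t_test_power(delta = 0.19, sd = 0.1, n = 5)
```

one-sided power above 80% (two-sided would be about 0.75, which is why the
directional default matters).

## Numerical and testing choices

* Closed-form expected utilities are verified against a horizon-$10^4$
  truncated-series oracle at relative tolerance $10^{-6}$ over hundreds of
  random parameterizations, and the atomized deviation payoff additionally
  against a Monte-Carlo relation-activation oracle within three standard
  errors (a fixed relative tolerance is not meaningful for a stochastic
  oracle at feasible replication counts).
* Indifference at the thresholds is checked to $10^{-9}$ absolute; random
  test parameterizations keep payoffs at O(100) points and
  $\beta \le 0.9$ so that this tolerance sits well above double-precision
  round-off of the EU expressions.
* Sampler uniformity is checked by a $\chi^2$ goodness-of-fit test on
  70,000 draws over the 70-graph support (fixed seed).
* *Type-I calibration.* On condition-neutral null experiments the H1
  rejection frequency is compared to the *attained* level of the exact
  Mann–Whitney test, not to nominal 0.05: a discrete exact test cannot
  reject at exactly 0.05, and at 7 vs 7 groups its largest attainable
  two-sided level is about 0.038. Two subtleties matter here. First, the
  null generator must be condition-neutral: trigger strategies with noise
  behave *differently* across information regimes (that is the cascade
  result), so an "identical mixture in both arms" trigger dataset is not a
  null for H1; the calibration uses history-independent cooperators with
  tremble 0.1, whose play is identically distributed in both arms. Second,
  the calibration is run at a problem size (hundreds to a thousand
  generated experiments) chosen to keep the whole suite's runtime modest
  while leaving the binomial check sharp.
* A floor effect worth knowing about: at tremble 0.02, nearly every
  embedded all-trigger group has fully collapsed by period 30, so in the
  late window (30–35) the embedded arm has *lower* across-group SD than
  the atomized arm — the higher-dispersion signature appears in the late
  window only at lower noise (e.g. 0.005), or over the full 1–35 window at
  0.02, where collapse timing still varies. The dispersion tests are
  written accordingly.

## Limitations

* The theory module covers the weak (partner-specific) trigger only; the
  strong trigger exists as a simulator strategy but no closed-form
  threshold is derived for it.
* Networks are complete and static: no partner choice, no restricted
  potential-partner sets, no imitation dynamics.
* The learning model is one defensible parameterization of aspiration
  reinforcement, not a fitted behavioral model.
* Synthetic data cannot stand in for the undeposited human data: the
  pipeline reproduces *procedures* and their operating characteristics,
  not the empirical findings.
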