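# rwcoop

Cooperation and reputation in networked repeated Prisoner's Dilemmas.

Does embedding interactions in a social network — so that third parties
hear about defections — make cooperation easier to sustain? The
Raub–Weesie model answers yes for rational, forward-looking actors:
reputation weakens the patience requirement for conditional cooperation.
`rwcoop` implements that model, the laboratory game built to test it, and
the group-level statistical analysis that goes with it, for researchers in
behavioral game theory and experimental social science who want to compute
the theory's predictions, probe its fragility to noise and learning, and
dry-run (or power) an experimental analysis on synthetic data.

## The model

`n` actors on a complete network; each period a uniform random `m`-regular
interaction graph is drawn and matched pairs play a simultaneous Prisoner's
Dilemma with payoffs `T > R > P > S`; unmatched relations pay `Q`; future
payoffs are discounted by `β`. A given relation is matched with probability
`π = m/(n−1)` per period. Trigger strategies (cooperate with a partner
until that partner is observed defecting, then defect against them forever)
are a mutual Nash equilibrium exactly when

- embedded information (everyone observes all outcomes):
  `β > (T−R)/(T−P) =: β_emb`
- atomized information (actors observe only their own interactions):
  `β > (T−R)/(T−P−(R−P)(1−π)) =: β_ato ≥ β_emb`

with equality iff `π = 1`; `Q` cancels. Under the standard lab
parameterization (`T=60, R=40, P=20, S=0, Q=30`, `n=6`, `m=2`, so
`π = 0.4`) the thresholds are `β_emb = 1/2 < β_ato = 5/7`: the embedded
regime sustains cooperation for less patient actors.

Around that core the package provides:

- `rw_model()` — the model object, with `coef()`, `predict()` (expected
  utilities and cooperation premia at stated `β`), `summary()`, `plot()`,
  and `simulate()` methods;
- `sample_matching()` — exactly uniform sampling of labeled `m`-regular
  interaction graphs (enumeration for small `n`, stub-pairing rejection —
  also exact — beyond);
- `run_group()` — an agent-based engine playing the exact experimental
  game under either information regime, with trigger, strong-trigger,
  unconditional, and Bush–Mosteller learning strategies, per-decision
  tremble noise, and injectable forced defections;
- `experiment_design()` / `generate_experiment()` — lab-shaped synthetic
  multi-group datasets (presets for a 7+7-group and a 6+6-group
  experiment), with CSV round-trip and structural validation;
- `group_cooperation_rate()`, `first_interaction_cooperation()`,
  `mann_whitney()` (exact permutation enumeration for N ≤ 20),
  `variance_comparison()`, `t_test_power()`, and
  `run_hypothesis_suite()` — the full group-level testing pipeline;
- `rwpd_main()` — a command-line entry point
  (`inst/scripts/rwpd`) with subcommands `theory`, `simulate`, `generate`,
  `analyze`, `power`, `replicate`.

## Worked example

```r
library(rwcoop)

mod <- rw_model()   # the lab parameterization
mod
#> Repeated Prisoner's Dilemma on a complete network
#> Prisoner's Dilemma payoffs (points):
#>   T = 60, R = 40, P = 20, S = 0; non-interaction Q = 30
#>   n = 6 actors, m = 2 partners/period, pi = m/(n-1) = 0.4
#> Threshold discount factors for conditional cooperation:
#>   embedded information:  beta_emb = 0.5
#>   atomized information:  beta_ato = 0.7143

predict(mod, beta = c(0.5, 5/7, 0.9))
#>        beta eu_all_c eu_all_d_embedded eu_all_d_atomized gap_embedded gap_atomized
#> 1 0.5000000      340               340          374.2857            0    -34.28571
#> 2 0.7142857      595               535          595.0000           60      0.00000
#> 3 0.9000000     1700              1380         1473.9130          320    226.08696
```

At `β = 1/2` cooperation and defection pay exactly the same under embedded
information (340 discounted points) while defection still wins under
atomized information (negative premium); at `β = 5/7` the atomized regime
reaches indifference too. The model's fragility to noise is a one-liner:

```r
rec <- run_group(group_config(condition = "embedded"),
                 strategies = strategy_spec("TRIGGER"), seed = 42,
                 inject = list(period = 1, actor = 1))
round(cooperation_trajectory(rec), 3)[1:8]
#>     1     2     3     4     5     6     7     8
#> 0.917 0.833 0.500 0.000 0.000 0.000 0.000 0.000
```

A single forced defection in period 1 cascades through the reputation
channel to universal defection by period 4; the same injection under
atomized information stays confined to one dyad for the whole game. The
full pipeline — generate a synthetic experiment, then test it — runs as:

```r
res <- replicate_experiment("exp1", seed = 1,
         mixture = strategy_mixture(TRIGGER = 1, tremble = 0.02))
res$report
#> == exp1 (embedded n = 7, atomized n = 7) ==
#> H1 main-window cooperation, embedded vs atomized:
#>   Exact Mann-Whitney U test (permutation enumeration): statistic = 0, p = 0.0005828 (two.sided; n = 7 vs 7)
#> ...
```

Here all seven embedded groups rank below all seven atomized groups
(U = 0, the exact two-sided floor of 2/3432): with trembling triggers,
reputation *lowers* cooperation.

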