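---
title: "Payoff-driven resource allocation in networked public goods games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Payoff-driven resource allocation in networked public goods games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pggalloc)
```

## The model

`pggalloc` simulates public goods games (PGGs) on networks in the
neighbourhood formulation: every node `j` hosts one game whose participants
are its neighbourhood `nu_j` — node `j` plus its `k_j` direct neighbours —
so a degree-`k` player takes part in `k + 1` games per round. Contributions
staked in a game are pooled, multiplied by the synergy factor `r`, and the
proceeds are shared equally among the `k_j + 1` participants regardless of
what each contributed. Players carry one of two strategies, cooperate
(`s = 1`, contribute) or defect (`s = 0`, free-ride).

Two budgeting schemes are supported. Under *fixed cost per player* (FCP),
the default, every player disposes of the same capital `c` per round,
however many games she plays; under *fixed cost per game* (FCG) she has `c`
per game, i.e. `(k + 1) c` per round.

The departure from the classical setting is how that capital is split.
Instead of an even `cap / (k + 1)` stake in every game, each player
redistributes her capital according to what each game paid her in the
previous round:

    I[i,j](t+1) = cap_i * exp(alpha * Pi[i,j](t)) / sum_{l in nu_i} exp(alpha * Pi[i,l](t))

a softmax over her `k_i + 1` per-game payoffs with intensity `alpha`.
`alpha = 0` recovers the classical even split; larger `alpha` concentrates
capital in the historically profitable games. At `t = 0` all payoffs are
zero and the split is even.

Per-game payoffs follow the standard sharing rule,

    Pi[i,j](t) = r / (k_j + 1) * sum_{l in nu_j} I[l,j](t) s_l(t)  -  I[i,j](t) s_i(t)

and a player's round payoff `Pi_i` is the sum over her `k_i + 1` games. The
bookkeeping identity `sum_i Pi_i = (r - 1) * total contributed` holds
exactly and is enforced by the tests.

At the end of each round all players revise their strategies
*synchronously*. The default rule is the finite-population analogue of the
replicator dynamics: player `i` compares payoffs with one uniformly chosen
neighbour `j` and, when `Pi_j > Pi_i`, copies `s_j` with probability
`(Pi_j - Pi_i) / M`. Unconditional imitation (copy the best of the
neighbourhood, self included) and the Fermi rule (logistic acceptance with
intensity `beta`) are available as robustness alternatives; all three leave
the all-cooperate and all-defect states absorbing.

## Parameters that matter

| parameter | meaning | default | notes |
|---|---|---|---|
| `r` | synergy multiplier on pooled contributions (dimensionless) | — | cooperation collapses near `r = 1`, saturates by `r = 6` |
| `c` | capital per round (FCP) or per game (FCG), currency units | 1 | sets the payoff scale |
| `alpha` | allocation intensity (dimensionless, >= 0) | 0 | 0 = classical even split; >= 2 gives strongly bimodal stakes |
| `scheme` | FCP or FCG budgeting | FCP | FCG scales a node's budget with its degree |
| `update_rule` | replicator / unconditional imitation / Fermi | replicator | |
| `beta` | Fermi selection intensity | 1 | not fixed by the replicator protocol; exposed and configurable |
| `t_relax`, `t_measure` | relaxation and measurement rounds | 5e4 / 1e3 | observables are time averages over the window |
| `n_runs` | independent replicates, fresh substrate each | 500 | |

The replicator normalization `M` must bound every payoff difference so that
imitation probabilities stay in `[0, 1]`. The package uses the analytic
bound `M = r c (k_max + 1) + c` under FCP (a defector whose co-players all
stake full capital in each shared game, versus a cooperator who recoups
nothing), with `c` replaced by `(k_max + 1) c` under FCG. Any valid bound
only rescales all imitation rates uniformly; the exact combinatorial
maximum would merely speed the dynamics up by a constant factor. The value
of `M` used is recorded in ensemble results and run manifests.

## The synthetic substrate

Games run on scale-free networks from the uncorrelated configuration model
(UCM): degrees are drawn i.i.d. from the truncated power law
`P(k) ~ k^-gamma` on `kmin..kmax`, stubs are matched uniformly at random,
and the structural cutoff `kmax = floor(sqrt(N))` keeps degree-degree
correlations out. The study defaults are `gamma = 2.5` and `kmin = 2` — the
latter guarantees every game has at least three players, so no game
degenerates into a two-player prisoner's dilemma — giving a mean degree of
about 4 (analytically 4.15 at `N = 10^4`).

Two sampling details are not fixed by the UCM recipe and were decided once:

* **Parity.** When the sampled degrees sum to an odd number, one uniformly
  chosen node is *resampled* until the sum is even, rather than bumping a
  degree by one; resampling leaves the marginal distribution of every node
  intact.
* **Defective matchings.** A stub matching that produces self-loops or
  multi-edges is discarded and redrawn; because the probability of an
  entirely clean matching is vanishingly small for heavy-tailed sequences,
  after `max_retries` failed attempts the last matching is repaired by
  random double-edge swaps that remove the defective pairs while preserving
  the degree sequence exactly. The handful of swapped pairs is a negligible
  perturbation of the uniform stub-matching ensemble.

The generator emulates the degree heterogeneity that drives the phenomena
studied here; it deliberately has no clustering, no degree correlations,
no community structure and no weighted or temporal edges, all of which real
social and economic networks possess. Passing tests therefore demonstrate
the mechanism on idealized scale-free substrates, not calibration to any
empirical network. Arbitrary external substrates can be supplied as
plain-text edge lists.

## Emergent observables

The analysis layer computes the quantities through which the model's
behaviour is read:

* `fraction_cooperators` — the steady-state cooperation level `f_c`.
* `investment_shares` — the distribution of `I[i,j] / cap_i`; for
  `alpha >= 2` it is strongly bimodal (a peak above 0.95 and one below
  0.05): players back one favourite game with nearly everything and keep
  token stakes elsewhere.
* `game_production` / `production_by_degree` — per-game normalized wealth
  `w_j = W_j / (k_j + 1)`, bounded by `c (r - 1)`; with even splitting it is
  homogeneous across degrees (mean near 0.5 at `r = 3.5`), with payoff-driven
  allocation low-degree games reach the maximum while hubs decline.
* `pareto_q` — the ranked fraction of games that produce a share `q` of
  total wealth; `q80` moves from roughly 70% under even splitting to near
  the 80–20 concentration for `alpha >= 2`.
* `classify_links` / `split_by_sign` / `backbone_metrics` — a directed
  participation is *negative* when the group would earn more without that
  contributor, i.e. `pot_j / (k_j + 1) < (pot_j - C[i,j]) / k_j`; positive
  links form a sparse near-tree backbone covering most nodes while negative
  links mirror the dense original graph.

The wheel graph (`make_wheel`) is kept as a closed-form testbed: under even
splitting, the hub's stake `c/(n+1)` in each leaf game is below the leaves'
`c/4`, so every hub participation in a leaf game is negative for all `r`
and `c`. Direct evaluation of the inequality with these stakes gives the
threshold `n > 3`; the tests assert the `n >= 5` regime, comfortably inside
it.

## Numerical choices

* Softmax rows are computed with the row maximum subtracted before
  exponentiation, so arbitrarily large payoffs cannot overflow; a test
  checks invariance under shifting a player's payoff row by a constant.
  Allocation rows reproduce the player's capital to 1e-9.
* The sign classification compares the two sides of the group inequality
  with a relative guard of 1e-9, so exact-equality configurations (equal
  contributions on regular graphs) classify as positive instead of being
  split by rounding noise. Equality is positive by convention: absence of
  such a link is not strictly beneficial.
* Defectors' notional allocations are updated every round from the payoffs
  they experience, so a defector who turns cooperator immediately invests
  according to her latest payoff profile; the allocation rule carries no
  strategy condition and only the strategy bit is copied during imitation.
* Each player participates in her own focal game (`I[i,i]` exists); the
  replicator and Fermi rules compare against proper neighbours only
  (self-comparison is a no-op), while unconditional imitation includes the
  player herself so that "keep" is expressible, with ties resolved in
  favour of keeping and otherwise uniformly among the best neighbours.
* Random draws are consumed in fixed node order per round, and per-run
  seeds derive from the master seed by a fixed counter rule
  (`derive_run_seed`), so ensembles are bit-reproducible; the fused C++
  round loop is tested to reproduce the per-operation R API exactly.
* Uniform-strategy absorption is detected and reported (`absorbed`,
  `t_absorbed`) but the loop always runs its full schedule: in an
  all-cooperator population the investment field keeps evolving and the
  wealth observables depend on it, so cutting the run short would freeze
  them prematurely. All-defect states are fully frozen after two rounds
  and cost little to finish.
* Link signs, shares and productions are computed from the
  measurement-window *time averages* of investments and contributions by
  default — the stabler reading of "at the steady state" — with the final
  instantaneous state exposed via `instantaneous = TRUE`.
* `pareto_q` breaks production ties by node index (stable sort), matching a
  brute-force subset enumeration oracle on small inputs.

## Problem sizes

The package defaults mirror the full study protocol (`N = 10^4`, 5x10^4
relaxation rounds, 10^3 measurement rounds, 500 replicates). The test suite
and the bundled acceptance checks run a scaled-down configuration chosen to
preserve the qualitative regime while staying desk-sized: `N = 2000`
(`kmax = 44`), 10^4 relaxation rounds, 10^3 measurement rounds, 10
replicates, with endpoint and property checks on still smaller fixtures
(`N` between 100 and 1000). At this scale the measured observables —
`q80` near 0.70 at `alpha = 0` versus near 0.22 at `alpha >= 2`, positive
backbone coverage above 0.98, mean normalized production near 0.46–0.48 at
`r = 3.5` — sit inside the stochastic tolerances applied to the reference
values, consistent with the size-robustness of the phenomenon.

## Limitations

* Strategy updating is synchronous only; asynchronous or stochastic-order
  updating is out of scope.
* No mutation/exploration noise and no capital accumulation: budgets reset
  every round.
* The backbone is characterized by coverage, edge ratio and component
  counts rather than a full topological comparison with the minimum
  spanning tree.
* Substrates beyond the UCM family (lattices, correlated or clustered
  graphs) are supported only through user-supplied edge lists, and no
  figure-drawing utilities are provided.
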