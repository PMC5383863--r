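# pggalloc

Agent-based simulation of **public goods games (PGGs) on networks with
payoff-driven resource allocation**, for researchers in evolutionary game
theory and the economics of cooperation who want to study how wealth
concentration and effective free-riding emerge from simple investment
feedback.

In the classical networked PGG every node `j` hosts a game among its
neighbourhood `nu_j` (itself plus its `k_j` neighbours); a cooperator splits
her per-round capital `c` evenly over her `k + 1` games, the pool of game
`j` is multiplied by the synergy factor `r` and shared equally. `pggalloc`
replaces the even split by a profit-chasing rule: player `i` stakes

```
I[i,j](t+1) = cap_i · exp(α Π[i,j](t)) / Σ_{l∈nu_i} exp(α Π[i,l](t))
```

on the game centred at `j`, where `Π[i,j](t)` is the payoff that game paid
her last round and the allocation intensity `α ≥ 0` interpolates between
the classical even split (`α = 0`) and aggressive concentration on the most
profitable game. Payoffs follow the standard sharing rule
`Π[i,j] = r/(k_j+1) Σ_l I[l,j] s_l − I[i,j] s_i`, and strategies evolve
synchronously by payoff-difference imitation (finite-population replicator;
unconditional imitation and the Fermi rule are available for robustness).

Beyond cooperation levels, the package measures the emergent organization:
bimodal investment-share distributions, degree-resolved wealth production,
the ranked-wealth statistic `q80` (fraction of games producing 80% of total
wealth, the Pareto 80–20 diagnostic), and the classification of every
directed participation as *positive* or *negative* — negative when the
group would earn more without that contributor — with the positive links
forming a sparse, near-tree backbone of the network.

Substrates are scale-free graphs from the uncorrelated configuration model
(`P(k) ~ k^−γ`, structural cutoff `kmax = √N`), deterministic test
topologies (wheel, ring, complete graph), or user-supplied plain-text edge
lists.

## Worked example

```r
library(pggalloc)

cfg <- sim_config(N = 500, gamma = 2.5, kmin = 2, kmax = 22,
                  r = 4, alpha = 2, t_relax = 4000, t_measure = 500,
                  n_runs = 5, master_seed = 42)
ens <- run_ensemble(cfg)
sprintf("steady-state cooperator fraction: %.3f +/- %.3f",
        ens$fc_mean, ens$fc_se)
#> steady-state cooperator fraction: 0.950 +/- 0.004

snap <- ens$runs[[1]]$snapshot           # window-averaged steady state
prod <- game_production(snap)
pareto_q(prod$w, 0.8)                    # q80, ranked-wealth concentration
#> 0.222

shares <- investment_shares(snap)$shares # bimodal stakes at alpha = 2
c(mean(shares > 0.95), mean(shares < 0.05))
#> 0.14 0.65

layers <- split_by_sign(snap$graph, classify_links(snap))
backbone_metrics(layers$positive, snap$graph)
#>  coverage n_edges edge_ratio components mean_degree
#>     0.988     531   1.064128         34       2.124
```

With `α = 2` at `r = 4`, cooperation is nearly full, yet only ~22% of the
games produce 80% of the wealth (the 80–20 concentration; at `α = 0` the
same statistic is near 70%), two-thirds of all stakes are token
contributions below 5% of a player's capital while one in seven is a
near-total bet on a favourite game, and the positive-link backbone touches
~99% of the nodes with roughly as many edges as a spanning tree.

A command-line front end wraps the same machinery:

```sh
Rscript inst/cli/pggsim.R simulate --config config.json --out-dir out/
Rscript inst/cli/pggsim.R sweep --config config.json --param r --values 1,2,3,4,5,6
Rscript inst/cli/pggsim.R analyze --dir out/
```

(after installation the script lives at
`system.file("cli", "pggsim.R", package = "pggalloc")`). Configs are flat
JSON key-value files mirroring `sim_config()`; every key is also a flag.
Results are TSV tables plus a JSON manifest of seeds and settings that
reproduces the run exactly.

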