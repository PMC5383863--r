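#' Game parameters
#'
#' Bundles the parameters of the networked public goods game. Each node `i`
#' plays the `k_i + 1` games centred on the members of its neighbourhood
#' `nu_i` (itself plus its neighbours). Under the fixed-cost-per-player (FCP)
#' scheme a cooperator has capital `c` per round split across all her games;
#' under fixed-cost-per-game (FCG) she has `c` per game, i.e. `(k_i + 1) c`
#' per round. The pooled contributions of a game are multiplied by the
#' synergy factor `r` and shared equally among its participants.
#'
#' `alpha` sets how aggressively capital chases past profits: the share of
#' capital sent to the game centred on `j` is proportional to
#' `exp(alpha * Pi[i,j])` where `Pi[i,j]` is last round's payoff from that
#' game. `alpha = 0` recovers the classical even split.
#'
#' @param r synergy factor (> 0).
#' @param c capital per round (FCP) or per game (FCG), > 0.
#' @param alpha allocation intensity (>= 0).
#' @param scheme `"FCP"` or `"FCG"`.
#' @param update_rule `"replicator"` (payoff-difference imitation normalized
#'   by the bound `M`), `"unconditional_imitation"` (copy the best of the
#'   neighbourhood), or `"fermi"` (logistic imitation with intensity `beta`).
#' @param beta Fermi selection intensity (> 0; only used by `"fermi"`).
#' @return An object of class `pgg_params`.
#' @export
game_params <- function(r, c = 1, alpha = 0,
                        scheme = c("FCP", "FCG"),
                        update_rule = c("replicator", "unconditional_imitation",
                                        "fermi"),
                        beta = 1) {
  scheme <- match.arg(scheme)
  update_rule <- match.arg(update_rule)
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("r must be a single number > 0")
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
    stop("c must be a single number > 0")
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha < 0)
    stop("alpha must be a single number >= 0")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("beta must be a single number > 0")
  structure(list(r = r, c = c, alpha = alpha, scheme = scheme,
                 update_rule = update_rule, beta = beta),
            class = "pgg_params")
}

# per-node capital per round
node_capital <- function(struct, params) {
  if (params$scheme == "FCP") rep.int(params$c, struct$N)
  else (struct$deg + 1) * params$c
}

.rule_code <- function(update_rule) {
  match(update_rule, c("replicator", "unconditional_imitation", "fermi")) - 1L
}

#' Initial game state
#'
#' Strategies are i.i.d. Bernoulli(`coop_prob`) (1 = cooperate, 0 = defect),
#' all payoffs start at zero, and — because there are no previous payoffs to
#' react to — every player's capital is split evenly over her `k_i + 1` games.
#'
#' @param g an `igraph` simple graph.
#' @param params a [game_params()] object.
#' @param seed optional integer seed (strategy draw).
#' @param coop_prob initial cooperation probability (default 0.5).
#' @return An object of class `pgg_state`: list with round index `t`,
#'   strategies `s`, per-pair investments `I`, per-pair payoffs `Pi_pair`,
#'   per-node payoff totals `Pi_tot`, per-game pots `pot`, capital `cap`, and
#'   the pair geometry `struct` (investor/focal indexing, 1-based in R).
#' @export
initial_state <- function(g, params, seed = NULL, coop_prob = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  if (coop_prob < 0 || coop_prob > 1) stop("coop_prob must be in [0, 1]")
  struct <- graph_structure(g)
  cap <- node_capital(struct, params)
  s <- rbinom(struct$N, 1L, coop_prob)
  I <- (cap / (struct$deg + 1))[struct$inv]
  P <- length(struct$inv)
  structure(list(t = 0L, s = as.integer(s), I = I,
                 Pi_pair = numeric(P), Pi_tot = numeric(struct$N),
                 pot = numeric(struct$N), cap = cap, struct = struct),
            class = "pgg_state")
}

#' Per-game payoffs
#'
#' For every participant `i` of the game centred on `j`:
#' `Pi[i,j] = r/(k_j+1) * sum_{l in nu_j} I[l,j] s_l  -  I[i,j] s_i`,
#' and the per-node total is the row sum over `j in nu_i`. The identity
#' `sum_i Pi_i = (r - 1) * (total capital contributed)` holds exactly.
#'
#' @inheritParams initial_state
#' @param state a `pgg_state`.
#' @return The state with `Pi_pair`, `Pi_tot` and per-game pots `pot` updated.
#' @export
compute_payoffs <- function(state, g, params) {
  st <- state$struct
  res <- cpp_payoffs(st$inv - 1L, st$focal - 1L, state$I, state$s, st$deg,
                     params$r)
  state$pot <- res$pot
  state$Pi_pair <- res$pi_pair
  state$Pi_tot <- res$pi_tot
  state
}

#' Payoff-driven reallocation of investments
#'
#' Sets next round's investments to
#' `I[i,j] = cap_i * exp(alpha * Pi[i,j]) / sum_{l in nu_i} exp(alpha * Pi[i,l])`,
#' computed with the row maximum subtracted before exponentiation so that any
#' finite payoffs are handled stably. Rows sum to the player's capital. The
#' rule is applied to every node regardless of its current strategy, so a
#' defector who turns cooperator immediately invests according to the payoff
#' profile she experienced.
#'
#' @inheritParams compute_payoffs
#' @return The state with `I` replaced by next round's allocation.
#' @export
allocate_investments <- function(state, g, params) {
  state$I <- cpp_allocate(state$Pi_pair, state$struct$inv_ptr, state$cap,
                          params$alpha)
  state
}

#' Replicator normalization constant
#'
#' An analytic upper bound `M` on the payoff difference between any two
#' players, used to map payoff differences to imitation probabilities in
#' `[0, 1]`. Under FCP, `M = r c (k_max + 1) + c`: a defector whose every
#' co-player commits full capital to each shared game earns at most
#' `r c (k_max + 1)`, while a cooperator who recoups nothing loses at most
#' `c`. Under FCG the per-round capital `c` is replaced by `(k_max + 1) c`.
#'
#' @inheritParams initial_state
#' @return A single positive number `M`.
#' @export
normalization_constant <- function(g, params) {
  kmax <- max(igraph::degree(g))
  if (params$scheme == "FCP") {
    params$r * params$c * (kmax + 1) + params$c
  } else {
    params$r * (kmax + 1) * params$c * (kmax + 1) + (kmax + 1) * params$c
  }
}

#' Synchronous strategy update
#'
#' All players revise simultaneously, based on the pre-update strategies and
#' payoff totals; random draws are consumed in node order for
#' reproducibility.
#'
#' * `replicator`: player `i` picks one neighbour `j` uniformly at random;
#'   if `Pi_j > Pi_i` she copies `s_j` with probability `(Pi_j - Pi_i)/M`,
#'   otherwise she keeps her strategy.
#' * `unconditional_imitation`: copy the strategy of the highest-earning
#'   member of the neighbourhood (self included); ties involving the player
#'   herself are kept, otherwise broken uniformly among the best neighbours.
#' * `fermi`: pick one neighbour `j` at random and copy with probability
#'   `1 / (1 + exp(-beta (Pi_j - Pi_i)))`.
#'
#' @inheritParams compute_payoffs
#' @param M normalization constant (required by the replicator rule); computed
#'   via [normalization_constant()] when `NULL`.
#' @return The state with `s` replaced by the post-update strategies.
#' @export
update_strategies <- function(state, g, params, M = NULL) {
  if (is.null(M)) M <- normalization_constant(g, params)
  st <- state$struct
  state$s <- cpp_update(state$s, state$Pi_tot, st$adj - 1L, st$adj_ptr,
                        .rule_code(params$update_rule), M, params$beta)
  state
}

#' Play one full round of all games
#'
#' Round order: (1) payoffs from the current investments and strategies;
#' (2) synchronous strategy update from the payoff totals; (3) reallocation
#' of next round's investments from this round's per-game payoffs — each
#' player reallocates from her own payoffs even if she just copied a
#' neighbour's strategy.
#'
#' @inheritParams update_strategies
#' @return The state at round `t + 1`.
#' @export
play_round <- function(state, g, params, M = NULL) {
  if (is.null(M)) M <- normalization_constant(g, params)
  state <- compute_payoffs(state, g, params)
  state <- update_strategies(state, g, params, M)
  state <- allocate_investments(state, g, params)
  state$t <- state$t + 1L
  state
}
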