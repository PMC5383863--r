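# Observables computed from a live `pgg_state` or a steady-state
# `pgg_snapshot`. For snapshots the measurement-window time averages are used
# by default (the stabler reading of "at the steady state"); pass
# `instantaneous = TRUE` to use the final-round investments and strategies
# instead. For a live state the current round is always used.

.params_of <- function(x, params) {
  if (!is.null(params)) return(params)
  if (!is.null(x$params)) return(x$params)
  stop("params must be supplied for a live game state")
}

.investments_of <- function(x, instantaneous) {
  if (inherits(x, "pgg_snapshot") && !instantaneous) x$avg_I else x$I
}

.contributions_of <- function(x, instantaneous) {
  if (inherits(x, "pgg_snapshot") && !instantaneous) x$avg_C
  else x$I * x$s[x$struct$inv]
}

#' Fraction of cooperators
#'
#' @param x a `pgg_state` or `pgg_snapshot`.
#' @return `sum(s)/N` in `[0, 1]` (final strategies for a snapshot).
#' @export
fraction_cooperators <- function(x) {
  mean(x$s)
}

#' Investment-share distribution
#'
#' The share of player `i`'s per-round capital invested in the game centred
#' on `j`, `I[i,j] / cap_i`, over all ordered participations. Per-node shares
#' sum to 1. At `alpha = 0` every share equals `1/(k_i+1)`; for strong
#' payoff-driven allocation the distribution becomes bimodal, with one peak
#' above 0.95 (the favourite game) and one below 0.05 (token stakes in the
#' rest).
#'
#' @param x a `pgg_state` or `pgg_snapshot`.
#' @param params a [game_params()] object (taken from the snapshot if `NULL`).
#' @param bins number of uniform histogram bins on `[0, 1]`.
#' @param cooperators_only drop rows of players whose (final) strategy is
#'   defect, whose allocations are notional (default `TRUE`).
#' @param instantaneous use the final-round investments instead of the
#'   window averages (snapshots only).
#' @return List with `shares` (numeric vector) and `hist`
#'   (`data.frame(mid, count, density)`).
#' @export
investment_shares <- function(x, params = NULL, bins = 100L,
                              cooperators_only = TRUE,
                              instantaneous = FALSE) {
  I <- .investments_of(x, instantaneous)
  shares <- I / x$cap[x$struct$inv]
  if (cooperators_only) shares <- shares[x$s[x$struct$inv] == 1L]
  shares <- pmin(pmax(shares, 0), 1)
  breaks <- seq(0, 1, length.out = bins + 1L)
  h <- graphics::hist(shares, breaks = breaks, plot = FALSE)
  list(shares = shares,
       hist = data.frame(mid = h$mids, count = h$counts, density = h$density))
}

#' Wealth produced per game
#'
#' The game centred on `j` produces `W_j = (r - 1) * sum_{l in nu_j} I[l,j] s_l`
#' (the sum of its participants' payoffs from that game) and the normalized
#' production is `w_j = W_j / (k_j + 1)`, bounded by `c (r - 1)` with equality
#' iff every participant commits her full capital to game `j`.
#'
#' @inheritParams investment_shares
#' @return `data.frame(node, degree, W, w)`, one row per focal node
#'   (1-based node ids).
#' @export
game_production <- function(x, params = NULL, instantaneous = FALSE) {
  params <- .params_of(x, params)
  contrib <- .contributions_of(x, instantaneous)
  st <- x$struct
  pot <- numeric(st$N)
  acc <- rowsum(contrib, st$focal)
  pot[as.integer(rownames(acc))] <- acc[, 1L]
  W <- (params$r - 1) * pot
  data.frame(node = seq_len(st$N), degree = st$deg, W = W,
             w = W / (st$deg + 1))
}

#' Normalized production resolved by degree
#'
#' Groups the per-game normalized productions `w_j` by the focal node's
#' degree.
#'
#' @inheritParams game_production
#' @return List with `per_game` (the [game_production()] table) and
#'   `per_degree` (`data.frame(degree, n, w_mean, w_sd)`).
#' @export
production_by_degree <- function(x, params = NULL, instantaneous = FALSE) {
  per_game <- game_production(x, params, instantaneous)
  agg <- aggregate(per_game$w, by = list(degree = per_game$degree),
                   FUN = function(v) c(n = length(v), mean = mean(v),
                                       sd = if (length(v) > 1L) sd(v) else 0))
  per_degree <- data.frame(degree = agg$degree,
                           n = agg$x[, "n"],
                           w_mean = agg$x[, "mean"],
                           w_sd = agg$x[, "sd"])
  list(per_game = per_game, per_degree = per_degree)
}

#' Ranked wealth-concentration fraction
#'
#' Sorts the per-game productions in decreasing order (ties broken by node
#' index) and returns the smallest fraction of games whose cumulative
#' production reaches a share `q` of the total. `pareto_q(w, 0.8)` is the
#' "what fraction of producers holds 80% of the wealth" statistic; a value
#' near 0.2 is the classical 80-20 concentration, a value near 0.7 a nearly
#' homogeneous economy.
#'
#' @param w non-negative productions, at least one strictly positive.
#' @param q target share of total production, in (0, 1].
#' @return `m / length(w)` where `m` is the minimal number of top-ranked
#'   games reaching the share `q`.
#' @export
pareto_q <- function(w, q = 0.8) {
  if (length(w) == 0L || any(!is.finite(w)) || any(w < 0))
    stop("w must be a non-empty vector of finite non-negative productions")
  if (q <= 0 || q > 1) stop("q must be in (0, 1]")
  total <- sum(w)
  if (total <= 0) stop("all productions are zero; ranked share is undefined")
  ord <- order(w, decreasing = TRUE)  # stable: ties keep node order
  cs <- cumsum(w[ord])
  m <- which(cs >= q * total - 1e-9 * total)[1L]
  m / length(w)
}

#' Classify directed participations as positive or negative
#'
#' Participant `i` of the game centred on `j` is a *negative* link when her
#' contribution is so small that the others would earn more without her:
#' `pot_j / (k_j + 1) < (pot_j - C[i,j]) / k_j` (strictly), where
#' `pot_j = sum_{l in nu_j} I[l,j] s_l` and `C[i,j] = I[i,j] s_i` is the
#' participant's contribution (the synergy factor multiplies both sides and
#' cancels). Equality — e.g. identical contributions on a regular graph — is
#' classified positive. Self-participations (`i == j`) are not classified.
#'
#' @inheritParams game_production
#' @return `data.frame(participant, focal, sign)` with one row per directed
#'   participation `i != j`; `sign` is `"positive"` or `"negative"`.
#' @export
classify_links <- function(x, params = NULL, instantaneous = FALSE) {
  params <- .params_of(x, params)
  contrib <- .contributions_of(x, instantaneous)
  st <- x$struct
  pot <- numeric(st$N)
  acc <- rowsum(contrib, st$focal)
  pot[as.integer(rownames(acc))] <- acc[, 1L]
  keep <- st$inv != st$focal
  inv <- st$inv[keep]; focal <- st$focal[keep]; cN <- contrib[keep]
  kj <- st$deg[focal]
  lhs <- params$r * pot[focal] / (kj + 1)
  rhs <- params$r * (pot[focal] - cN) / kj
  # strict inequality with a relative guard so exact-equality cases
  # (identical contributions) are not split by rounding noise
  tol <- 1e-9 * pmax(1, abs(rhs))
  data.frame(participant = inv, focal = focal,
             sign = ifelse(rhs - lhs > tol, "negative", "positive"))
}

#' Split the network by link sign
#'
#' Projects the directed sign table back onto the undirected edges: an edge
#' `{i, j}` joins the positive subgraph if either directed participation
#' (`i` in `j`'s game or `j` in `i`'s game) is positive, and the negative
#' subgraph if either is negative (an edge can appear in both layers). Both
#' subgraphs keep the full vertex set.
#'
#' @param g the original `igraph` graph.
#' @param signs a [classify_links()] table for `g`.
#' @return List with `positive` and `negative` igraph subgraphs.
#' @export
split_by_sign <- function(g, signs) {
  a <- pmin(signs$participant, signs$focal)
  b <- pmax(signs$participant, signs$focal)
  key <- paste(a, b)
  pos_keys <- unique(key[signs$sign == "positive"])
  neg_keys <- unique(key[signs$sign == "negative"])
  N <- igraph::vcount(g)
  edge_graph <- function(keys) {
    if (length(keys) == 0L)
      return(igraph::make_empty_graph(N, directed = FALSE))
    ends <- do.call(rbind, strsplit(keys, " "))
    gg <- igraph::graph_from_edgelist(
      cbind(as.integer(ends[, 1L]), as.integer(ends[, 2L])),
      directed = FALSE)
    igraph::add_vertices(gg, N - igraph::vcount(gg))
  }
  list(positive = edge_graph(pos_keys), negative = edge_graph(neg_keys))
}

#' Backbone metrics of a sign layer
#'
#' Summary statistics used to compare the positive layer with a spanning
#' tree of the original graph: node coverage (fraction of nodes incident to
#' at least one edge of the layer), the edge count relative to the `N - 1`
#' edges of a spanning tree, the number of connected components and the mean
#' degree.
#'
#' @param subgraph one layer from [split_by_sign()].
#' @param g the original graph (fixes the vertex set).
#' @return `data.frame(coverage, n_edges, edge_ratio, components, mean_degree)`.
#' @export
backbone_metrics <- function(subgraph, g) {
  N <- igraph::vcount(g)
  deg <- igraph::degree(subgraph)
  data.frame(coverage = mean(deg > 0),
             n_edges = igraph::ecount(subgraph),
             edge_ratio = igraph::ecount(subgraph) / (N - 1),
             components = igraph::components(subgraph)$no,
             mean_degree = mean(deg))
}
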