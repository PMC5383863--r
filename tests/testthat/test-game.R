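test_that("initial state splits capital evenly and respects coop_prob", {
  g <- make_wheel(5)
  p <- game_params(r = 4, c = 1)
  st <- initial_state(g, p, seed = 1, coop_prob = 1)
  expect_true(all(st$s == 1))
  # FCP: a degree-3 ring node spreads c = 1 over its 4 games
  ring_pairs <- st$struct$inv == 1
  expect_equal(st$I[ring_pairs], rep(0.25, 4))
  # hub (degree 5) spreads over 6 games
  hub_pairs <- st$struct$inv == 6
  expect_equal(st$I[hub_pairs], rep(1 / 6, 6))
  expect_true(all(st$Pi_pair == 0))

  pg <- game_params(r = 4, c = 1, scheme = "FCG")
  sg <- initial_state(g, pg, seed = 1, coop_prob = 1)
  expect_equal(sg$I[sg$struct$inv == 1], rep(1, 4))  # c per game

  s0 <- initial_state(g, p, seed = 2, coop_prob = 0)
  expect_true(all(s0$s == 0))
})

test_that("softmax allocation reproduces hand-evaluated shares", {
  g <- igraph::make_graph(c(1, 2), directed = FALSE)
  p <- game_params(r = 2, c = 1, alpha = 1)
  st <- initial_state(g, p, coop_prob = 1)
  # node 1 plays games focal {1,2}: payoffs (1, 0)
  st$Pi_pair <- c(1, 0, 0, 0)
  st <- allocate_investments(st, g, p)
  e <- exp(1)
  expect_equal(st$I[1:2], c(e / (e + 1), 1 / (e + 1)), tolerance = 1e-12)

  g3 <- make_ring(3)
  p4 <- game_params(r = 2, c = 1, alpha = 4)
  st3 <- initial_state(g3, p4, coop_prob = 1)
  # node 1 has payoffs (2, 0, 0) over its three games
  st3$Pi_pair[st3$struct$inv == 1] <- c(2, 0, 0)
  st3 <- allocate_investments(st3, g3, p4)
  expect_equal(st3$I[st3$struct$inv == 1][1], 1 / (1 + 2 * exp(-8)),
               tolerance = 1e-12)
})

test_that("allocation rows always sum to the player's capital", {
  g <- make_wheel(7)
  for (alpha in c(0, 1, 4)) {
    for (scheme in c("FCP", "FCG")) {
      p <- game_params(r = 4, c = 1, alpha = alpha, scheme = scheme)
      st <- initial_state(g, p, seed = 3)
      set.seed(alpha * 10 + 1)
      st$Pi_pair <- rnorm(length(st$I), sd = 5)
      st <- allocate_investments(st, g, p)
      sums <- rowsum(st$I, st$struct$inv)[, 1]
      expect_equal(sums, unname(st$cap), tolerance = 1e-9,
                   ignore_attr = TRUE)
      expect_true(all(st$I >= 0))
      if (alpha == 0)
        expect_equal(st$I, (st$cap / (st$struct$deg + 1))[st$struct$inv])
    }
  }
})

test_that("allocation is invariant under shifting a player's payoffs", {
  g <- make_wheel(6)
  p <- game_params(r = 4, c = 1, alpha = 2)
  st <- initial_state(g, p, seed = 5)
  set.seed(9)
  st$Pi_pair <- rnorm(length(st$I), sd = 3)
  a <- allocate_investments(st, g, p)$I
  # add a different constant to each player's payoff row
  shift <- (1:igraph::vcount(g) * 7)[st$struct$inv]
  st$Pi_pair <- st$Pi_pair + shift
  b <- allocate_investments(st, g, p)$I
  expect_equal(a, b, tolerance = 1e-9)
  # extreme payoffs stay finite thanks to the max-shift
  st$Pi_pair <- st$Pi_pair + 5000
  expect_true(all(is.finite(allocate_investments(st, g, p)$I)))
})

test_that("payoffs match hand evaluation and conserve total wealth", {
  # triangle, all cooperators, alpha = 0, c = 1, r = 2
  g <- make_ring(3)
  p <- game_params(r = 2, c = 1, alpha = 0)
  st <- initial_state(g, p, coop_prob = 1)
  st <- compute_payoffs(st, g, p)
  expect_equal(st$Pi_pair, rep(1 / 3, 9), tolerance = 1e-12)
  expect_equal(st$Pi_tot, rep(1, 3), tolerance = 1e-12)
  expect_equal(sum(st$Pi_tot), (p$r - 1) * sum(st$I * st$s[st$struct$inv]))

  # all defectors earn nothing
  st0 <- initial_state(g, p, coop_prob = 0)
  st0 <- compute_payoffs(st0, g, p)
  expect_true(all(st0$Pi_pair == 0))

  # conservation on random mixed states of a heterogeneous graph
  gh <- build_ucm_graph(sample_degree_sequence(100, 2.5, 2, 10, seed = 7),
                        seed = 8)
  ph <- game_params(r = 3.5, c = 1, alpha = 2)
  for (seed in 1:5) {
    sth <- initial_state(gh, ph, seed = seed, coop_prob = 0.5)
    set.seed(seed + 100)
    sth$Pi_pair <- rnorm(length(sth$I), sd = 2)
    sth <- allocate_investments(sth, gh, ph)
    sth <- compute_payoffs(sth, gh, ph)
    invested <- sum(sth$I * sth$s[sth$struct$inv])
    expect_equal(sum(sth$Pi_tot), (ph$r - 1) * invested,
                 tolerance = 1e-6 * igraph::vcount(gh) / max(1, invested))
  }
})

test_that("a full-capital game pays every participant c(r-1)", {
  g <- make_complete(4)
  p <- game_params(r = 3.5, c = 1)
  st <- initial_state(g, p, coop_prob = 1)
  st$I[] <- 0
  st$I[st$struct$focal == 1] <- 1  # everyone stakes c = 1 on node 1's game
  st <- compute_payoffs(st, g, p)
  expect_equal(st$Pi_pair[st$struct$focal == 1], rep(2.5, 4))
})

test_that("normalization constant bounds every payoff difference", {
  edge <- igraph::make_graph(c(1, 2), directed = FALSE)
  expect_equal(normalization_constant(edge, game_params(r = 2, c = 1)), 5)
  expect_equal(normalization_constant(make_wheel(5), game_params(r = 3, c = 1)),
               19)
  # simulate a trajectory; no adjacent payoff gap may exceed M
  g <- make_wheel(8)
  p <- game_params(r = 4, c = 1, alpha = 2)
  M <- normalization_constant(g, p)
  st <- initial_state(g, p, seed = 11)
  for (t in 1:50) {
    st <- play_round(st, g, p, M)
    ends <- igraph::as_edgelist(g)
    gaps <- abs(st$Pi_tot[ends[, 1]] - st$Pi_tot[ends[, 2]])
    expect_true(all(gaps <= M))
  }
})

test_that("replicator imitation has the stated linear probabilities", {
  g <- igraph::make_graph(c(1, 2), directed = FALSE)
  p <- game_params(r = 2, c = 1)
  M <- normalization_constant(g, p)
  base <- initial_state(g, p, coop_prob = 1)
  base$s <- c(0L, 1L)

  # equal payoffs: never copy
  base$Pi_tot <- c(1, 1)
  set.seed(1)
  for (k in 1:20) expect_equal(update_strategies(base, g, p, M)$s, c(0L, 1L))

  # difference M: copy with certainty
  base$Pi_tot <- c(0, M)
  set.seed(2)
  st2 <- update_strategies(base, g, p, M)
  expect_equal(st2$s[1], 1L)
  expect_equal(st2$s[2], 1L)  # the richer player keeps her strategy

  # difference M/4: empirical copy rate near 0.25
  base$Pi_tot <- c(0, M / 4)
  set.seed(3)
  copies <- replicate(4000, update_strategies(base, g, p, M)$s[1])
  expect_lt(abs(mean(copies) - 0.25), 3 * sqrt(0.25 * 0.75 / 4000))
})

test_that("unconditional imitation copies the best neighbourhood strategy", {
  g <- make_ring(4)  # neighbours of 1 are 2 and 4
  p <- game_params(r = 2, c = 1, update_rule = "unconditional_imitation")
  st <- initial_state(g, p, coop_prob = 1)
  st$s <- c(1L, 0L, 1L, 0L)
  # own payoff strictly highest: keep
  st$Pi_tot <- c(10, 1, 1, 1)
  expect_equal(update_strategies(st, g, p)$s[1], 1L)
  # neighbour 2 strictly best: copy its defection
  st$Pi_tot <- c(0, 5, 0, 1)
  expect_equal(update_strategies(st, g, p)$s[1], 0L)
  # tie with self: keep
  st$Pi_tot <- c(5, 5, 0, 1)
  expect_equal(update_strategies(st, g, p)$s[1], 1L)
})

test_that("Fermi imitation follows the logistic curve", {
  g <- igraph::make_graph(c(1, 2), directed = FALSE)
  p <- game_params(r = 2, c = 1, update_rule = "fermi", beta = 1)
  st <- initial_state(g, p, coop_prob = 1)
  st$s <- c(0L, 1L)
  # equal payoffs: copy with probability 1/2
  st$Pi_tot <- c(2, 2)
  set.seed(4)
  copies <- replicate(4000, update_strategies(st, g, p)$s[1])
  expect_lt(abs(mean(copies) - 0.5), 3 * sqrt(0.25 / 4000))
  # steep beta, clear winner: copy almost surely
  psteep <- game_params(r = 2, c = 1, update_rule = "fermi", beta = 50)
  st$Pi_tot <- c(0, 2)
  set.seed(5)
  copies <- replicate(200, update_strategies(st, g, psteep)$s[1])
  expect_true(all(copies == 1L))
})

test_that("parameter validation names the offending argument", {
  expect_error(game_params(r = -1), "r")
  expect_error(game_params(r = 2, c = 0), "c")
  expect_error(game_params(r = 2, alpha = -0.5), "alpha")
  expect_error(game_params(r = 2, beta = 0), "beta")
  expect_error(game_params(r = 2, scheme = "XXX"), "FCP")
})
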