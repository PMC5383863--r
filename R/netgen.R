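#' Sample a truncated power-law degree sequence
#'
#' Draws `N` i.i.d. degrees from the normalized truncated power law
#' \eqn{P(k) \propto k^{-\gamma}} on the support `kmin..kmax`. If the resulting
#' stub count is odd, the degree of one uniformly chosen node is redrawn until
#' the total is even, which leaves the marginal distribution of every other
#' node untouched.
#'
#' @param N number of nodes (>= 3).
#' @param gamma power-law exponent (> 1).
#' @param kmin,kmax inclusive degree bounds; `kmax` defaults to
#'   `floor(sqrt(N))`, the structural cutoff that keeps the configuration
#'   model free of degree-degree correlations.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return An object of class `pgg_degseq`: list with `degrees`, `N`, `gamma`,
#'   `kmin`, `kmax`.
#' @examples
#' ds <- sample_degree_sequence(100, gamma = 2.5, kmin = 2, seed = 1)
#' mean(ds$degrees)
#' @export
sample_degree_sequence <- function(N, gamma, kmin = 2L, kmax = floor(sqrt(N)),
                                   seed = NULL) {
  N <- as.integer(N)
  kmin <- as.integer(kmin); kmax <- as.integer(kmax)
  if (N < 3L) stop("N must be >= 3")
  if (gamma <= 1) stop("gamma must be > 1")
  if (kmin < 1L || kmin > kmax) stop("invalid bounds: need 1 <= kmin <= kmax")
  if (kmax >= N) stop("invalid bounds: kmax must be <= N - 1")
  if (!is.null(seed)) set.seed(seed)
  support <- kmin:kmax
  draw <- if (length(support) == 1L) {
    function(n) rep.int(support, n)
  } else {
    prob <- support^(-gamma)
    function(n) sample(support, n, replace = TRUE, prob = prob)
  }
  degrees <- draw(N)
  if (sum(degrees) %% 2L == 1L) {
    i <- sample.int(N, 1L)
    for (tries in seq_len(10000L)) {
      degrees[i] <- draw(1L)
      if (sum(degrees) %% 2L == 0L) break
    }
    if (sum(degrees) %% 2L == 1L)
      stop("could not make the degree sum even by resampling one node; ",
           "the support may contain only one parity")
  }
  structure(list(degrees = degrees, N = N, gamma = gamma,
                 kmin = kmin, kmax = kmax),
            class = "pgg_degseq")
}

#' Build an uncorrelated configuration-model graph
#'
#' Realizes a degree sequence as a simple undirected graph by random stub
#' matching: each node gets as many half-edges as its degree and the pool of
#' stubs is paired uniformly at random. A matching containing self-loops or
#' multi-edges is discarded and redrawn; after `max_retries` failed matchings
#' the last one is repaired by random double-edge swaps, which preserves the
#' degree sequence exactly while removing the defective pairs.
#'
#' @param ds a `pgg_degseq` or a plain integer degree vector (even sum,
#'   graphical in the Erdős–Gallai sense).
#' @param seed optional integer seed.
#' @param max_retries full-restart attempts before switching to swap repair.
#' @return An `igraph` simple undirected graph whose degree sequence equals
#'   `ds` exactly. Vertices are `1..N` in R (`0..N-1` in edge-list files).
#' @export
build_ucm_graph <- function(ds, seed = NULL, max_retries = 50L) {
  degrees <- if (inherits(ds, "pgg_degseq")) ds$degrees else as.integer(ds)
  N <- length(degrees)
  if (any(degrees < 0L)) stop("degrees must be non-negative")
  if (sum(degrees) %% 2L == 1L) stop("degree sum must be even")
  if (!igraph::is_graphical(degrees))
    stop("degree sequence is not graphical (fails the Erdős–Gallai condition)")
  if (!is.null(seed)) set.seed(seed)
  stubs <- rep.int(seq_len(N), degrees)
  m <- length(stubs) %/% 2L
  ends <- NULL
  for (attempt in seq_len(max(1L, max_retries))) {
    perm <- sample(stubs)
    u <- perm[seq_len(m) * 2L - 1L]
    v <- perm[seq_len(m) * 2L]
    a <- pmin(u, v); b <- pmax(u, v)
    key <- as.numeric(a) * N + b
    if (!any(a == b) && !anyDuplicated(key)) {
      ends <- cbind(a, b)
      break
    }
    last <- list(a = a, b = b, key = key)
  }
  if (is.null(ends))
    ends <- .repair_matching(last$a, last$b, last$key, N)
  g <- igraph::graph_from_edgelist(ends, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, N - igraph::vcount(g)))
  stopifnot(igraph::is_simple(g),
            identical(as.integer(igraph::degree(g)), as.integer(degrees)))
  g
}

# Double-edge-swap repair: repeatedly pick a defective edge (self-loop or one
# instance of a duplicated pair) and a random partner edge, and rewire the four
# endpoints; accepted only when both replacement edges are simple and new.
.repair_matching <- function(a, b, key, N) {
  m <- length(a)
  counts <- new.env(hash = TRUE, parent = emptyenv())
  for (k in key) {
    ck <- as.character(k)
    counts[[ck]] <- (if (is.null(counts[[ck]])) 0L else counts[[ck]]) + 1L
  }
  has <- function(k) {
    ck <- as.character(k)
    !is.null(counts[[ck]]) && counts[[ck]] > 0L
  }
  bump <- function(k, d) {
    ck <- as.character(k)
    counts[[ck]] <- (if (is.null(counts[[ck]])) 0L else counts[[ck]]) + d
  }
  bad <- function() which(a == b | duplicated(key))
  bad_idx <- bad()
  max_iter <- 2000L + 400L * length(bad_idx)
  iter <- 0L
  while (length(bad_idx) > 0L) {
    iter <- iter + 1L
    if (iter > max_iter)
      stop("double-edge-swap repair failed to produce a simple graph")
    e <- bad_idx[1L]
    f <- sample.int(m, 1L)
    if (f == e) next
    # two ways to cross the pairs; pick one at random
    if (sample.int(2L, 1L) == 1L) {
      e1 <- c(a[e], a[f]); e2 <- c(b[e], b[f])
    } else {
      e1 <- c(a[e], b[f]); e2 <- c(b[e], a[f])
    }
    na1 <- min(e1); nb1 <- max(e1)
    na2 <- min(e2); nb2 <- max(e2)
    if (na1 == nb1 || na2 == nb2) next
    k1 <- as.numeric(na1) * N + nb1
    k2 <- as.numeric(na2) * N + nb2
    if (k1 == k2 || has(k1) || has(k2)) next
    bump(key[e], -1L); bump(key[f], -1L)
    a[e] <- na1; b[e] <- nb1; key[e] <- k1; bump(k1, 1L)
    a[f] <- na2; b[f] <- nb2; key[f] <- k2; bump(k2, 1L)
    bad_idx <- bad()
  }
  cbind(a, b)
}

#' Deterministic test topologies
#'
#' `make_wheel(n)` builds a ring of `n` nodes each linked to its two ring
#' neighbours and to a central hub (node `n+1` in R indexing, `n` in 0-based
#' files): `n+1` nodes, `2n` edges, hub degree `n`, ring degrees 3.
#' `make_ring(n)` is the cycle graph (all degrees 2) and `make_complete(n)`
#' the complete graph.
#'
#' @param n ring length / node count (>= 3).
#' @return An `igraph` simple undirected graph.
#' @export
make_wheel <- function(n) {
  n <- as.integer(n)
  if (n < 3L) stop("n must be >= 3")
  ring <- cbind(seq_len(n), c(seq_len(n)[-1L], 1L))
  spokes <- cbind(seq_len(n), rep.int(n + 1L, n))
  igraph::graph_from_edgelist(rbind(ring, spokes), directed = FALSE)
}

#' @rdname make_wheel
#' @export
make_ring <- function(n) {
  n <- as.integer(n)
  if (n < 3L) stop("n must be >= 3")
  igraph::make_ring(n)
}

#' @rdname make_wheel
#' @export
make_complete <- function(n) {
  n <- as.integer(n)
  if (n < 3L) stop("n must be >= 3")
  igraph::make_full_graph(n)
}

#' Read / write plain-text edge lists
#'
#' One edge per line as two whitespace-separated 0-based integer node ids;
#' lines starting with `#` are comments. Self-loops, duplicate edges and
#' malformed lines are rejected with the offending line number.
#'
#' @param path file path.
#' @return `read_edge_list` returns an `igraph` graph with `max(id) + 1`
#'   vertices; `write_edge_list` returns `path` invisibly.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  u <- integer(0); v <- integer(0)
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[[ln]])
    if (raw == "" || startsWith(raw, "#")) next
    tok <- strsplit(raw, "[[:space:]]+")[[1L]]
    if (length(tok) != 2L || anyNA(suppressWarnings(as.integer(tok))))
      stop("malformed edge on line ", ln, ": '", raw, "'")
    i <- as.integer(tok[1L]); j <- as.integer(tok[2L])
    if (i < 0L || j < 0L) stop("negative node id on line ", ln)
    if (i == j) stop("self-loop on line ", ln, ": '", raw, "'")
    u <- c(u, i); v <- c(v, j)
  }
  if (length(u) == 0L) stop("edge list is empty: ", path)
  key <- paste(pmin(u, v), pmax(u, v))
  if (anyDuplicated(key)) {
    ln_bad <- which(duplicated(key))[1L]
    stop("duplicate edge on line ",
         .edge_line_number(lines, ln_bad), ": '",
         paste(u[ln_bad], v[ln_bad]), "'")
  }
  igraph::graph_from_edgelist(cbind(u, v) + 1L, directed = FALSE)
}

# map the index of the k-th edge back to its file line (skipping comments)
.edge_line_number <- function(lines, k) {
  n <- 0L
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[[ln]])
    if (raw == "" || startsWith(raw, "#")) next
    n <- n + 1L
    if (n == k) return(ln)
  }
  NA_integer_
}

#' @rdname read_edge_list
#' @param g an `igraph` graph to write.
#' @export
write_edge_list <- function(g, path) {
  ends <- igraph::as_edgelist(g, names = FALSE) - 1L
  a <- pmin(ends[, 1L], ends[, 2L]); b <- pmax(ends[, 1L], ends[, 2L])
  o <- order(a, b)
  writeLines(paste(a[o], b[o]), path)
  invisible(path)
}

# Internal graph geometry shared by the game engine: CSR adjacency (sorted
# neighbor lists) and the directed participation pairs (investor, focal) with
# focal ranging over nu_i = {i} + neighbors(i), grouped by investor.
graph_structure <- function(g) {
  N <- igraph::vcount(g)
  if (N < 1L) stop("graph has no vertices")
  if (!igraph::is_simple(g)) stop("graph must be simple (no loops/multi-edges)")
  nbr <- igraph::as_adj_list(g)
  nbr <- lapply(nbr, function(x) sort(as.integer(x)))
  deg <- lengths(nbr)
  games <- lapply(seq_len(N), function(i) sort(c(i, nbr[[i]])))
  inv <- rep.int(seq_len(N), deg + 1L)
  focal <- unlist(games, use.names = FALSE)
  inv_ptr <- c(0L, cumsum(deg + 1L))
  adj <- unlist(nbr, use.names = FALSE)
  if (is.null(adj)) adj <- integer(0)
  adj_ptr <- c(0L, cumsum(deg))
  list(N = N, deg = as.integer(deg),
       inv = as.integer(inv), focal = as.integer(focal),
       inv_ptr = as.integer(inv_ptr),
       adj = as.integer(adj), adj_ptr = as.integer(adj_ptr))
}
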