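# Brute-force graph oracles, written independently of the package
# implementation: plain BFS for distances and geodesic counts, exhaustive
# triangle enumeration for clustering. Used to cross-check every metric on
# small graphs.

oracle_bfs <- function(adj, s) {
  n <- ncol(adj)
  dist <- rep(Inf, n)
  nsp <- rep(0, n)          # number of shortest paths from s
  dist[s] <- 0; nsp[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in which(adj[v, ] == 1)) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1) nsp[w] <- nsp[w] + nsp[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, nsp = nsp)
}

oracle_distances <- function(adj) {
  n <- ncol(adj)
  t(vapply(seq_len(n), function(s) oracle_bfs(adj, s)$dist, numeric(n)))
}

oracle_clustering <- function(adj) {
  n <- ncol(adj)
  cc <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      tri <- tri + adj[nb[a], nb[b]]
    }
    2 * tri / (k * (k - 1))
  }, numeric(1))
  mean(cc)
}

oracle_lp <- function(adj) {
  d <- oracle_distances(adj)
  off <- d[upper.tri(d)]
  list(lp = mean(off[is.finite(off)]), unreachable = sum(is.infinite(off)))
}

oracle_eglob <- function(adj) {
  d <- oracle_distances(adj)
  off <- d[upper.tri(d)]
  mean(1 / off)
}

oracle_ne <- function(adj) {
  d <- oracle_distances(adj)
  n <- ncol(adj)
  vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    mean(1 / di)
  }, numeric(1))
}

oracle_nle <- function(adj) {
  n <- ncol(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    oracle_eglob(adj[nb, nb, drop = FALSE])
  }, numeric(1))
}

oracle_eloc <- function(adj) mean(oracle_nle(adj))

# Betweenness by explicit geodesic counting: for every source s, BFS gives
# distances and path counts; the dependency of a pair (s, t) on i is
# nsp(s,i) * nsp(i,t) / nsp(s,t) when i lies on a geodesic.
oracle_bc <- function(adj) {
  n <- ncol(adj)
  bfs <- lapply(seq_len(n), function(s) oracle_bfs(adj, s))
  bc <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    dst <- bfs[[s]]$dist[t]
    if (is.infinite(dst)) next
    for (i in seq_len(n)) {
      if (i == s || i == t) next
      if (bfs[[s]]$dist[i] + bfs[[i]]$dist[t] == dst) {
        bc[i] <- bc[i] + bfs[[s]]$nsp[i] * bfs[[i]]$nsp[t] / bfs[[s]]$nsp[t]
      }
    }
  }
  bc
}

# Deterministic random simple graph; guarantees at least one edge.
random_adj <- function(n, p = 0.4, seed = 1) {
  withr::with_seed(seed, {
    repeat {
      adj <- matrix(0L, n, n)
      ut <- which(upper.tri(adj))
      on <- ut[runif(length(ut)) < p]
      if (length(on) >= 1) break
    }
    adj[on] <- 1L
    adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
    adj
  })
}

graph_from_edges <- function(n, edges, labels = NULL) {
  adj <- matrix(0L, n, n)
  for (e in edges) {
    adj[e[1], e[2]] <- adj[e[2], e[1]] <- 1L
  }
  if (!is.null(labels)) dimnames(adj) <- list(labels, labels)
  binary_graph(adj)
}

ring_lattice_adj <- function(n, k) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n)) for (o in seq_len(k %/% 2)) {
    j <- ((i - 1 + o) %% n) + 1
    adj[i, j] <- adj[j, i] <- 1L
  }
  adj
}
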