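# Independent graph oracles, written against a plain adjacency list so they
# share no code with the igraph-backed implementation.

# adjacency list (list of integer vectors) from a two-column edge matrix
adjFromEdges <- function(edges, n) {
  adj <- rep(list(integer()), n)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      u <- edges[k, 1]; v <- edges[k, 2]
      adj[[u]] <- union(adj[[u]], v)
      adj[[v]] <- union(adj[[v]], u)
    }
  }
  adj
}

# single-source BFS distances; unreachable = Inf
bfsDistances <- function(adj, src) {
  n <- length(adj)
  dist <- rep(Inf, n)
  dist[src] <- 0
  frontier <- src
  while (length(frontier)) {
    nxt <- integer()
    for (u in frontier) {
      for (v in adj[[u]]) {
        if (is.infinite(dist[v])) {
          dist[v] <- dist[u] + 1
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

# number of distinct geodesics between src and every node (BFS path counting)
bfsPathCounts <- function(adj, src) {
  dist <- bfsDistances(adj, src)
  n <- length(adj)
  cnt <- numeric(n)
  cnt[src] <- 1
  ord <- order(dist)
  for (u in ord) {
    if (is.infinite(dist[u])) next
    for (v in adj[[u]]) {
      if (dist[v] == dist[u] + 1) cnt[v] <- cnt[v] + cnt[u]
    }
  }
  list(dist = dist, count = cnt)
}

# normalized betweenness of every node by brute-force pair accumulation
bruteBetweenness <- function(adj) {
  n <- length(adj)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    fs <- bfsPathCounts(adj, s)
    for (t in seq(s + 1, n)) {
      if (is.infinite(fs$dist[t]) || fs$dist[t] == 0) next
      ft <- bfsPathCounts(adj, t)
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (fs$dist[v] + ft$dist[v] == fs$dist[t])
          btw[v] <- btw[v] + fs$count[v] * ft$count[v] / fs$count[t]
      }
    }
  }
  btw / ((n - 1) * (n - 2) / 2)
}

# Erdos-Renyi edge matrix (may be disconnected)
randomEdges <- function(n, p) {
  pairs <- t(combn(n, 2))
  pairs[runif(nrow(pairs)) < p, , drop = FALSE]
}

cycleNet <- function(n, operant = 1L) {
  behavioralNetwork(cbind(seq_len(n), c(seq_len(n)[-1], 1L)), n, operant)
}

starNet <- function(n, center = 1L) {
  leaves <- setdiff(seq_len(n), center)
  behavioralNetwork(cbind(center, leaves), n, center)
}
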