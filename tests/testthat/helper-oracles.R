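# Independent brute-force oracles used to validate the graph statistics.
# Deliberately written without igraph: plain adjacency lists, BFS queues,
# and exhaustive path enumeration.

# edges: 2-column character matrix -> named adjacency list
oracle_adjlist <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(as.vector(edges)))
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

# single-source BFS distances (Inf when unreachable)
oracle_bfs <- function(adj, source) {
  dist <- setNames(rep(Inf, length(adj)), names(adj))
  dist[source] <- 0
  queue <- source
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (u in adj[[v]]) {
      if (is.infinite(dist[u])) {
        dist[u] <- dist[v] + 1
        queue <- c(queue, u)
      }
    }
  }
  dist
}

oracle_distances <- function(adj) {
  t(vapply(names(adj), function(s) oracle_bfs(adj, s), numeric(length(adj))))
}

# enumerate every shortest s->t path by DFS over the BFS-distance DAG
oracle_all_shortest_paths <- function(adj, s, t, dist_from_s) {
  if (is.infinite(dist_from_s[t])) return(list())
  walk <- function(v) {
    if (v == s) return(list(s))
    preds <- adj[[v]][dist_from_s[adj[[v]]] == dist_from_s[v] - 1]
    out <- list()
    for (p in preds) {
      for (pp in walk(p)) out[[length(out) + 1]] <- c(pp, v)
    }
    out
  }
  walk(t)
}

# normalized betweenness by exhaustive shortest-path enumeration
oracle_betweenness <- function(edges, nodes = NULL) {
  adj <- oracle_adjlist(edges, nodes)
  vs <- names(adj)
  n <- length(vs)
  b <- setNames(rep(0, n), vs)
  if (n < 3) return(b)
  for (i in 1:(n - 1)) {
    dist <- oracle_bfs(adj, vs[i])
    for (j in (i + 1):n) {
      paths <- oracle_all_shortest_paths(adj, vs[i], vs[j], dist)
      if (length(paths) == 0) next
      for (p in paths) {
        inner <- setdiff(p, c(vs[i], vs[j]))
        for (v in inner) b[v] <- b[v] + 1 / length(paths)
      }
    }
  }
  b / ((n - 1) * (n - 2) / 2)
}

oracle_closeness <- function(edges, nodes = NULL) {
  adj <- oracle_adjlist(edges, nodes)
  d <- oracle_distances(adj)
  diag(d) <- Inf
  apply(d, 1, function(row) {
    r <- row[is.finite(row)]
    if (length(r) == 0) 0 else 1 / mean(r)
  })
}

oracle_cpl <- function(edges, nodes = NULL) {
  adj <- oracle_adjlist(edges, nodes)
  d <- oracle_distances(adj)
  v <- d[upper.tri(d)]
  mean(v[is.finite(v) & v > 0])
}

# k-core numbers by repeated pruning of minimum-degree vertices
oracle_coreness <- function(edges, nodes = NULL) {
  adj <- oracle_adjlist(edges, nodes)
  core <- setNames(rep(0L, length(adj)), names(adj))
  remaining <- names(adj)
  k <- 0L
  while (length(remaining) > 0) {
    degs <- vapply(remaining, function(v) length(intersect(adj[[v]], remaining)), integer(1))
    if (min(degs) > k) k <- min(degs)
    drop <- remaining[degs <= k]
    core[drop] <- k
    remaining <- setdiff(remaining, drop)
  }
  core
}

# upper-tail hypergeometric by exhaustive subset enumeration (tiny N only)
oracle_hyper_enum <- function(k, K, N, n) {
  universe <- seq_len(N)
  hits_in <- seq_len(K)  # first K elements carry the annotation
  draws <- combn(N, n)
  good <- apply(draws, 2, function(s) sum(s %in% hits_in) >= k)
  mean(good)
}

# seeded random simple graph on n named nodes, edge probability p
oracle_random_graph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("X%02d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  list(nodes = nodes, edges = pairs[keep, , drop = FALSE])
}

# netpharm network from an oracle edge matrix, keeping isolated nodes
net_from_oracle <- function(edges, nodes) {
  g <- netpharm::network_from_edges(edges)
  iso <- setdiff(nodes, igraph::V(g)$name)
  if (length(iso)) g <- igraph::add_vertices(g, length(iso), name = iso)
  g
}

table1_degree_sequence <- function() c(7, 6, 6, 6, 5, 5, 5, 4, 4, 4, 3, 3, 2, 2)
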