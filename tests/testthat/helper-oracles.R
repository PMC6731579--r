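# Independent brute-force oracles, written against a plain adjacency list
# (no igraph algorithms): BFS distances, exhaustive geodesic enumeration,
# betweenness by path-fraction sums, and coreness by naive repeated peeling.

adjacency_list <- function(net) {
  el <- igraph::as_edgelist(net, names = TRUE)
  nodes <- igraph::V(net)$name
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) adj[[v]] <- character(0)
  if (nrow(el)) {
    for (r in seq_len(nrow(el))) {
      adj[[el[r, 1]]] <- c(adj[[el[r, 1]]], el[r, 2])
      adj[[el[r, 2]]] <- c(adj[[el[r, 2]]], el[r, 1])
    }
  }
  adj
}

oracle_bfs_dist <- function(adj, s) {
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- unique(nxt)
  }
  dist
}

# all geodesics s -> t: DFS along strictly distance-increasing steps
oracle_geodesics <- function(adj, s, t) {
  dist <- oracle_bfs_dist(adj, s)
  if (is.infinite(dist[t])) return(list())
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (w in adj[[v]]) {
      if (dist[w] == dist[v] + 1 && dist[w] <= dist[t]) walk(c(path, w))
    }
  }
  walk(s)
  paths
}

# raw (unnormalised) node and edge betweenness over unordered pairs,
# endpoints excluded for the node case
oracle_betweenness <- function(net) {
  adj <- adjacency_list(net)
  nodes <- names(adj)
  nb <- stats::setNames(rep(0, length(nodes)), nodes)
  eb <- list()
  ekey <- function(a, b) paste0(min(a, b), "|", max(a, b))
  n <- length(nodes)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        paths <- oracle_geodesics(adj, nodes[i], nodes[j])
        if (!length(paths)) next
        npaths <- length(paths)
        for (p in paths) {
          if (length(p) > 2) {
            for (mid in p[-c(1, length(p))]) nb[mid] <- nb[mid] + 1 / npaths
          }
          for (e in seq_len(length(p) - 1)) {
            k <- ekey(p[e], p[e + 1])
            eb[[k]] <- (if (is.null(eb[[k]])) 0 else eb[[k]]) + 1 / npaths
          }
        }
      }
    }
  }
  list(node = nb, edge = unlist(eb))
}

# coreness by naive repeated peeling: shell k removes all nodes of
# degree <= k, cascading, before moving to k + 1
oracle_coreness <- function(net) {
  adj <- adjacency_list(net)
  ks <- stats::setNames(rep(NA_integer_, length(adj)), names(adj))
  k <- 0L
  while (anyNA(ks)) {
    repeat {
      alive <- names(adj)[is.na(ks[names(adj)])]
      degs <- vapply(adj[alive], function(nb) sum(is.na(ks[nb])), numeric(1))
      peel <- alive[degs <= k]
      if (!length(peel)) break
      ks[peel] <- k
    }
    adj <- adj[names(adj)[is.na(ks[names(adj)])]]
    k <- k + 1L
  }
  ks
}

# uniform random simple graph on n labelled vertices with edge prob p;
# every vertex kept (isolated vertices allowed)
random_graph <- function(n, p = 0.4) {
  nodes <- paste0("v", seq_len(n))
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p
  coexpression_network(as.data.frame(pairs[keep, , drop = FALSE]),
                       nodes = nodes)
}
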