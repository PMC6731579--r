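#' Topology summary of a coexpression network
#'
#' Computes the six per-node / per-edge topological properties used
#' throughout the package and their network averages: degree, local
#' clustering coefficient (and global transitivity), shortest path length,
#' node betweenness, edge betweenness, and k-shell coreness, plus the
#' degree-conditioned clustering profile c(k).
#'
#' Conventions: betweenness sums path fractions over unordered vertex pairs
#' with endpoints excluded (node case) and is not normalised; the average
#' path length is taken over connected pairs only; local clustering of a
#' vertex with fewer than two neighbours is 0; isolated vertices have
#' coreness 0.
#'
#' @param net a [coexpression_network()] (any undirected simple igraph works).
#' @return an object of class `topology_summary`: a list with scalar fields
#'   `n_nodes`, `n_edges`, `avg_degree`, `avg_clustering`,
#'   `global_transitivity`, `avg_pathlength`, `pathlength_defined`,
#'   `avg_node_betweenness`, `avg_edge_betweenness`, `avg_coreness`; vector
#'   fields `degree`, `clustering`, `node_betweenness`, `coreness` (named by
#'   gene), `edge_betweenness` (named `"a|b"`), and `ck_profile` (named by
#'   degree).
#' @examples
#' k4 <- coexpression_network(t(utils::combn(paste0("g", 1:4), 2)))
#' ts <- topology_summary(k4)
#' ts$avg_degree  # 3 for the complete graph on four vertices
#' @export
topology_summary <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0L) stop("topology_summary: empty network")
  m <- igraph::ecount(net)
  nm <- igraph::V(net)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))

  deg <- igraph::degree(net)
  names(deg) <- nm
  cc <- igraph::transitivity(net, type = "localundirected", isolates = "zero")
  names(cc) <- nm
  glob <- igraph::transitivity(net, type = "globalundirected")
  if (is.nan(glob)) glob <- 0

  if (n == 1L || m == 0L) {
    avg_l <- 0
    l_def <- FALSE
  } else {
    avg_l <- igraph::mean_distance(net, directed = FALSE, unconnected = TRUE)
    l_def <- is.finite(avg_l)
    if (!l_def) avg_l <- 0
  }

  nb <- igraph::betweenness(net, directed = FALSE, normalized = FALSE)
  names(nb) <- nm
  if (m > 0L) {
    eb <- igraph::edge_betweenness(net, directed = FALSE)
    el <- igraph::as_edgelist(net, names = TRUE)
    names(eb) <- edge_key(el[, 1], el[, 2])
  } else {
    eb <- numeric(0)
  }

  ks <- kshell_decomposition(net)

  has_k <- deg > 0
  ck <- if (any(has_k)) {
    tapply(cc[has_k], deg[has_k], mean)
  } else {
    numeric(0)
  }

  structure(list(
    n_nodes = n, n_edges = m,
    avg_degree = mean(deg), degree = deg,
    avg_clustering = mean(cc), clustering = cc,
    global_transitivity = glob,
    avg_pathlength = avg_l, pathlength_defined = l_def,
    avg_node_betweenness = mean(nb), node_betweenness = nb,
    avg_edge_betweenness = if (m > 0L) mean(eb) else 0,
    edge_betweenness = eb,
    avg_coreness = mean(ks), coreness = ks,
    ck_profile = ck
  ), class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf(
    paste0("topology summary: %d nodes, %d edges\n",
           "  <d> = %.4g   <c> = %.4g   transitivity = %.4g\n",
           "  <l> = %.4g%s   <b> = %.4g   <B> = %.4g   <ks> = %.4g\n"),
    x$n_nodes, x$n_edges, x$avg_degree, x$avg_clustering,
    x$global_transitivity, x$avg_pathlength,
    if (x$pathlength_defined) "" else " (undefined)",
    x$avg_node_betweenness, x$avg_edge_betweenness, x$avg_coreness))
  invisible(x)
}

#' k-shell decomposition
#'
#' Assigns each gene its coreness by iterative peeling: isolated genes form
#' the 0-shell; then all genes of degree <= k are removed (cascading) to
#' define shell k, for k = 1, 2, ... until the network is exhausted.
#'
#' @param net a coexpression network.
#' @return named integer vector of corenesses, one per gene.
#' @export
kshell_decomposition <- function(net) {
  n <- igraph::vcount(net)
  nm <- igraph::V(net)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  if (n == 0L) return(stats::setNames(integer(0), character(0)))
  ks <- igraph::coreness(net)
  ks <- as.integer(ks)
  names(ks) <- nm
  ks
}

#' Shortest-path census
#'
#' Exact counts of shortest paths for every connected unordered pair of
#' genes, together with the number of those geodesics passing through each
#' intermediate gene and each edge. Intended for the small and medium graphs
#' on which exhaustive geodesic enumeration is feasible; the betweenness
#' fields of [topology_summary()] use the same conventions and scale to
#' large networks.
#'
#' @param net a coexpression network.
#' @return list of class `shortest_path_census` with components
#'   `pair_counts` (named by `"j|k"`), `through_node` (named `"j|k@i"`) and
#'   `through_edge` (named `"j|k@a|b"`); only nonzero through-counts are kept.
#' @export
shortest_path_census <- function(net) {
  nm <- igraph::V(net)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(net)))
  pair_counts <- numeric(0)
  through_node <- new.env(parent = emptyenv())
  through_edge <- new.env(parent = emptyenv())
  n <- length(nm)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      targets <- nm[(i + 1L):n]
      asp <- suppressWarnings(
        igraph::all_shortest_paths(net, from = nm[i], to = targets,
                                   mode = "all"))
      paths <- asp$vpaths %||% asp$res
      for (p in paths) {
        vseq <- nm[as.integer(p)]
        j <- vseq[1]; k <- vseq[length(vseq)]
        if (j == k) next
        key <- edge_key(j, k)
        pair_counts[key] <- (if (is.na(pair_counts[key])) 0 else pair_counts[key]) + 1
        if (length(vseq) > 2L) {
          for (mid in vseq[-c(1L, length(vseq))]) {
            nk <- paste0(key, "@", mid)
            assign(nk, get0(nk, envir = through_node, ifnotfound = 0) + 1,
                   envir = through_node)
          }
        }
        for (e in seq_len(length(vseq) - 1L)) {
          ek <- paste0(key, "@", edge_key(vseq[e], vseq[e + 1L]))
          assign(ek, get0(ek, envir = through_edge, ifnotfound = 0) + 1,
                 envir = through_edge)
        }
      }
    }
  }
  structure(list(
    pair_counts = pair_counts,
    through_node = unlist(as.list(through_node)) %||% numeric(0),
    through_edge = unlist(as.list(through_edge)) %||% numeric(0)
  ), class = "shortest_path_census")
}

#' Betweenness recomputed from a shortest-path census
#'
#' Sums path fractions n_jk(i)/n_jk (node case, endpoints excluded) and
#' n_jk(E)/n_jk (edge case) over unordered pairs. Used to cross-check the
#' betweenness fields of [topology_summary()].
#'
#' @param census a [shortest_path_census()].
#' @return list with named numeric vectors `node` and `edge`.
#' @export
census_betweenness <- function(census) {
  node <- numeric(0)
  edge <- numeric(0)
  split_at <- function(keys) {
    at <- regexpr("@", keys, fixed = TRUE)
    list(pair = substr(keys, 1L, at - 1L),
         who = substr(keys, at + 1L, nchar(keys)))
  }
  if (length(census$through_node)) {
    parts <- split_at(names(census$through_node))
    frac <- census$through_node / census$pair_counts[parts$pair]
    node <- vapply(split(frac, parts$who), sum, numeric(1))
  }
  if (length(census$through_edge)) {
    parts <- split_at(names(census$through_edge))
    frac <- census$through_edge / census$pair_counts[parts$pair]
    edge <- vapply(split(frac, parts$who), sum, numeric(1))
  }
  list(node = node, edge = edge)
}

# canonical unordered key "a|b" with a < b
edge_key <- function(a, b) {
  lo <- ifelse(a < b, a, b)
  hi <- ifelse(a < b, b, a)
  paste0(lo, "|", hi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
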