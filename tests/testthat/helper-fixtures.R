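# Small named graphs used across tests.

complete_graph <- function(n, prefix = "g") {
  coexpression_network(t(utils::combn(paste0(prefix, seq_len(n)), 2)))
}

path_graph <- function(labels = c("a", "b", "c")) {
  coexpression_network(data.frame(a = labels[-length(labels)], b = labels[-1]))
}

star_graph <- function(n_leaves = 5, center = "hub") {
  coexpression_network(data.frame(a = center, b = paste0("leaf", seq_len(n_leaves))))
}

cycle_graph <- function(n = 4) {
  v <- paste0("c", seq_len(n))
  coexpression_network(data.frame(a = v, b = c(v[-1], v[1])))
}

# edge set as a sorted character vector of "a|b" keys
edge_set <- function(net) {
  el <- igraph::as_edgelist(net, names = TRUE)
  sort(paste0(pmin(el[, 1], el[, 2]), "|", pmax(el[, 1], el[, 2])))
}
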