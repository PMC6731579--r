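#' Construct a coexpression network
#'
#' A coexpression network is an undirected simple graph whose vertices are
#' gene identifiers. It is represented as an [igraph::igraph] object with
#' vertex names; optional evolutionary annotations (age branch, repartitioned
#' branch, origination mechanism) are stored as vertex attributes.
#'
#' @param edges two-column data frame (or matrix) of gene-id pairs, one row
#'   per undirected edge. Character ids.
#' @param nodes optional character vector of gene ids; isolated genes that
#'   appear here but not in `edges` are kept as degree-0 vertices.
#' @param annotations optional data frame with column `gene` plus any of
#'   `branch` (integer 0-13), `new_branch` (integer 0-6), `mechanism`
#'   (`"duplication"`, `"de_novo"` or `"ancestral"`) and `parent`
#'   (gene id of the duplication parent, when known).
#' @return an igraph graph with class `c("coexpression_network", "igraph")`.
#' @examples
#' net <- coexpression_network(data.frame(a = c("g1", "g2"), b = c("g2", "g3")))
#' igraph::vcount(net)
#' @export
coexpression_network <- function(edges = NULL, nodes = NULL, annotations = NULL) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    el <- matrix(character(0), ncol = 2)
  } else {
    el <- as.matrix(as.data.frame(edges)[, 1:2])
    storage.mode(el) <- "character"
  }
  if (any(el[, 1] == el[, 2])) {
    stop("self-loops are not allowed in a coexpression network")
  }
  verts <- unique(c(as.character(nodes), as.vector(t(el))))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  missing_v <- setdiff(verts, igraph::V(g)$name)
  if (length(missing_v)) g <- igraph::add_vertices(g, length(missing_v), name = missing_v)
  if (igraph::any_multiple(g)) {
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  }
  if (!is.null(annotations)) g <- annotate_network(g, annotations)
  class(g) <- unique(c("coexpression_network", class(g)))
  g
}

#' Attach evolutionary annotations to a network
#'
#' @param net a coexpression network (igraph).
#' @param annotations data frame with column `gene` and any of `branch`,
#'   `new_branch`, `mechanism`, `parent` (see [coexpression_network()]).
#' @return the network with vertex attributes set for annotated genes;
#'   genes absent from `annotations` keep `NA`.
#' @export
annotate_network <- function(net, annotations) {
  ann <- as.data.frame(annotations)
  if (!"gene" %in% names(ann)) stop("annotations need a 'gene' column")
  if (anyDuplicated(ann$gene)) stop("duplicated gene ids in annotations")
  idx <- match(igraph::V(net)$name, ann$gene)
  for (col in intersect(c("branch", "new_branch", "mechanism", "parent"), names(ann))) {
    net <- igraph::set_vertex_attr(net, col, value = ann[[col]][idx])
  }
  net
}

#' Extract the annotation table of a network
#'
#' @param net a coexpression network.
#' @return data frame with one row per vertex and whichever of `branch`,
#'   `new_branch`, `mechanism`, `parent` are present as vertex attributes.
#' @export
network_annotations <- function(net) {
  out <- data.frame(gene = igraph::V(net)$name, stringsAsFactors = FALSE)
  for (col in intersect(c("branch", "new_branch", "mechanism", "parent"),
                        igraph::vertex_attr_names(net))) {
    out[[col]] <- igraph::vertex_attr(net, col)
  }
  out
}

#' Read an undirected edge list from delimited text
#'
#' Expects two columns (gene_a, gene_b); a header row is detected and kept
#' if the first line is non-numeric in both columns (any header names are
#' accepted). Extra columns are ignored.
#'
#' @param path file path.
#' @param sep field separator, default `","`.
#' @return a [coexpression_network()].
#' @export
read_edges <- function(path, sep = ",") {
  df <- utils::read.table(path, sep = sep, header = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character",
                          comment.char = "")
  if (ncol(df) < 2) stop("edge list needs at least two columns: ", path)
  # drop a header row if present (heuristic: both fields repeat nowhere as ids
  # is not checkable; accept common header spellings or identical first line)
  first <- tolower(as.character(df[1, 1:2]))
  if (all(grepl("^(gene|node|from|to|source|target|a|b|v1|v2)", first))) {
    df <- df[-1, , drop = FALSE]
  }
  coexpression_network(df[, 1:2])
}

#' Write a network as a two-column edge list
#'
#' @param net a coexpression network.
#' @param path output file path.
#' @param sep field separator, default `","`.
#' @return `path`, invisibly.
#' @export
write_edges <- function(net, path, sep = ",") {
  el <- igraph::as_edgelist(net, names = TRUE)
  df <- data.frame(gene_a = el[, 1], gene_b = el[, 2])
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression network: %d genes, %d links\n",
              igraph::vcount(x), igraph::ecount(x)))
  ann <- intersect(c("branch", "new_branch", "mechanism"),
                   igraph::vertex_attr_names(x))
  if (length(ann)) cat("annotations:", paste(ann, collapse = ", "), "\n")
  invisible(x)
}
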