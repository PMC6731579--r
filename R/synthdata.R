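#' Generate a block-correlated expression matrix
#'
#' Genes are grouped into blocks sharing a latent tissue profile; each
#' gene's expression is the block factor plus independent Gaussian noise.
#' Within-block Pearson correlation is then 1 / (1 + noise_sd^2) in
#' expectation and between-block correlation is near 0, which lets one
#' calibrate the noise to any target correlation: for the default
#' `noise_sd = 0.5` the expected within-block r is 0.8, comfortably above a
#' 0.7 link threshold.
#'
#' @param n_genes total number of genes.
#' @param n_tissues number of tissues (>= 3).
#' @param n_blocks number of coexpression blocks (genes split as evenly as
#'   possible).
#' @param noise_sd per-gene noise standard deviation (the latent factor has
#'   unit variance).
#' @param seed integer seed.
#' @return numeric matrix genes x tissues with rownames `g1..`, colnames
#'   `t1..`, and attribute `block` (integer block id per gene).
#' @export
make_expression <- function(n_genes, n_tissues = 10, n_blocks = 2,
                            noise_sd = 0.5, seed = 1L) {
  if (n_tissues < 3) stop("need at least 3 tissues")
  if (n_genes < 1 || n_blocks < 1) stop("counts must be positive")
  old_rng <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_rng)) assign(".Random.seed", old_rng, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  block <- rep(seq_len(n_blocks), length.out = n_genes)
  factors <- matrix(stats::rnorm(n_blocks * n_tissues), nrow = n_blocks)
  expr <- factors[block, , drop = FALSE] +
    matrix(stats::rnorm(n_genes * n_tissues, sd = noise_sd), nrow = n_genes)
  rownames(expr) <- paste0("g", seq_len(n_genes))
  colnames(expr) <- paste0("t", seq_len(n_tissues))
  attr(expr, "block") <- block
  expr
}

#' Generate a heavy-tailed seed network
#'
#' Preferential-attachment (Barabasi-Albert) construction: each new vertex
#' attaches `m` edges to existing vertices with probability proportional to
#' degree, yielding a connected graph with a heavy-tailed degree
#' distribution — a stand-in for the ancestral coexpression network.
#'
#' @param n number of genes.
#' @param m edges added per new vertex: a single integer, or a length-2
#'   range `c(lo, hi)` from which each vertex draws its edge count
#'   uniformly. A scalar `m` yields constant coreness (every vertex ends in
#'   the m-shell); the range form produces the dispersed coreness profile
#'   of real coexpression networks and is what coreness-sensitive
#'   simulations should use.
#' @param seed integer seed.
#' @param prefix gene-id prefix (default `"anc"`).
#' @return a [coexpression_network()] with `new_branch = 0` and
#'   `mechanism = "ancestral"` annotations.
#' @export
make_seed_graph <- function(n, m = 3, seed = 1L, prefix = "anc") {
  if (n < 2) stop("need at least 2 genes")
  old_rng <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_rng)) assign(".Random.seed", old_rng, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  if (length(m) == 2) {
    out_seq <- sample(seq(m[1], m[2]), n, replace = TRUE)
    out_seq <- pmin(out_seq, seq_len(n) - 1L)  # cannot exceed prior vertices
    g <- igraph::sample_pa(n, out.seq = out_seq, directed = FALSE)
  } else {
    g <- igraph::sample_pa(n, m = m, directed = FALSE)
  }
  g <- igraph::set_vertex_attr(g, "name", value = paste0(prefix, seq_len(n)))
  g <- igraph::set_vertex_attr(g, "new_branch", value = rep(0L, n))
  g <- igraph::set_vertex_attr(g, "mechanism", value = rep("ancestral", n))
  g <- igraph::set_vertex_attr(g, "parent", value = rep(NA_character_, n))
  class(g) <- unique(c("coexpression_network", class(g)))
  g
}

#' Forward-simulate an age-annotated network series with known truth
#'
#' Runs the improved growth model at known parameters over a 6-step (or
#' arbitrary-length) schedule, labelling every added gene with its branch
#' and origination mechanism and recording its true parent. The output has
#' the same shape as a real age-stratified series and is the ground-truth
#' fixture for estimator-recovery tests.
#'
#' @param seed_net ancestral network (default: [make_seed_graph()] with 500
#'   genes); all its genes are branch 0 ancestrals.
#' @param schedule list/matrix of per-step `c(n_dup, n_novo)` counts
#'   (default six steps of 50 duplicates + 5 de novo genes).
#' @param truth an [evolution_params()] holding the generating parameters.
#' @param seed integer seed.
#' @return list: `series` (networks 0..k), `annotations` (gene, new_branch,
#'   mechanism, parent), `truth`, `events` (full event log), `counts`
#'   (per-branch added-gene counts in the shape of
#'   [default_generation_counts()]).
#' @export
make_annotated_series <- function(seed_net = make_seed_graph(500, seed = seed),
                                  schedule = rep(list(c(50, 5)), 6),
                                  truth = evolution_params(alpha = 0.13,
                                                           beta = 0.80,
                                                           gamma = 1.0),
                                  seed = 1L) {
  run <- run_evolution(seed_net, schedule, truth, model = "model1",
                       seed = seed, topology = FALSE)
  final <- run$series[[length(run$series)]]
  ann <- network_annotations(final)
  ev <- run$events
  counts <- do.call(rbind, lapply(sort(unique(ev$step)), function(s) {
    data.frame(new_branch = s,
               n_new = sum(ev$step == s),
               n_dup = sum(ev$step == s & ev$type == "duplication"),
               n_novo = sum(ev$step == s & ev$type == "de_novo"))
  }))
  list(series = run$series, annotations = ann, truth = truth,
       events = ev, counts = counts)
}
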