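#' Evolution parameter set
#'
#' Bundles the wiring parameters and per-Myr generation rates used by the
#' growth simulators. `alpha` is the edge reservation rate of duplicate
#' genes, `beta` their rewiring rate, `gamma` the connection rate of de
#' novo genes (all as fractions of, respectively, the parent degree and the
#' ancestral mean degree); `delta` is the edge-removal probability of the
#' duplication-only baseline and defaults to `1 - alpha`.
#'
#' @param alpha reservation rate in `[0, 1]` (default 0.1289).
#' @param beta rewiring rate, nonnegative (default 0.7977).
#' @param gamma de novo connection rate, nonnegative (default 0.9929).
#' @param delta baseline removal probability (default `1 - alpha`).
#' @param r_dup,r_novo generation rates in genes/Myr (defaults 3.58, 0.31).
#' @return list of class `evolution_params`.
#' @export
evolution_params <- function(alpha = 0.1289, beta = 0.7977, gamma = 0.9929,
                             delta = 1 - alpha, r_dup = 3.58, r_novo = 0.31) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (beta < 0 || gamma < 0) stop("beta and gamma must be nonnegative")
  if (delta < 0 || delta > 1) stop("delta must be in [0, 1]")
  if (r_dup < 0 || r_novo < 0) stop("generation rates must be nonnegative")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
                 r_dup = r_dup, r_novo = r_novo, r_new = r_dup + r_novo),
            class = "evolution_params")
}

# round-half-up to nearest integer (the bracket [.] of the growth rules)
round_half_up <- function(x) floor(x + 0.5)

# deterministic per-event seed derived from a step seed, below 2^31-1
event_seed <- function(seed, i) {
  as.integer((as.double(seed %% 2147483647L) * 48271 + i) %% 2147483647)
}

#' Frozen snapshot of an ancestral network
#'
#' All wiring probabilities within one evolutionary step are computed from
#' the pre-step network; this captures the quantities the samplers need:
#' per-gene degree and coreness, the mean degree, adjacency (neighbour
#' sets), and (optionally) per-edge betweenness.
#'
#' @param net the ancestral network.
#' @param edge_betweenness compute ancestral edge betweenness (needed for
#'   betweenness-weighted edge retention; default TRUE).
#' @return list of class `network_snapshot`.
#' @export
network_snapshot <- function(net, edge_betweenness = TRUE) {
  nm <- igraph::V(net)$name
  deg <- igraph::degree(net)
  names(deg) <- nm
  ks <- kshell_decomposition(net)
  nbrs <- lapply(igraph::adjacent_vertices(net, igraph::V(net)),
                 function(v) nm[as.integer(v)])
  names(nbrs) <- nm
  eb <- NULL
  if (edge_betweenness && igraph::ecount(net) > 0) {
    ebv <- igraph::edge_betweenness(net, directed = FALSE)
    el <- igraph::as_edgelist(net, names = TRUE)
    eb <- stats::setNames(ebv, edge_key(el[, 1], el[, 2]))
  }
  structure(list(genes = nm, degree = deg, coreness = ks,
                 mean_degree = mean(deg), neighbours = nbrs,
                 edge_betweenness = eb),
            class = "network_snapshot")
}

#' Select a parent gene uniformly at random
#'
#' Each ancestral gene is equally likely (probability 1/N) to be chosen as
#' the parent of a duplication event. Uses the current RNG state.
#'
#' @param snapshot a [network_snapshot()] (or a coexpression network).
#' @return a gene id.
#' @export
select_parent <- function(snapshot) {
  genes <- if (inherits(snapshot, "network_snapshot")) snapshot$genes
           else igraph::V(snapshot)$name
  if (!length(genes)) stop("cannot select a parent from an empty network")
  genes[sample.int(length(genes), 1L)]
}

#' Retain parental edges with betweenness-weighted sampling
#'
#' A duplicate initially inherits all parental edges; exactly
#' `round(alpha * d_p)` of them (half-up, clamped to `[0, d_p]`) are kept.
#' Retention is a weighted draw without replacement with per-edge weight
#' `1 - B_ik / sum(B_ij)`, so high-betweenness parental edges are the ones
#' preferentially lost. When all weights vanish (a single parental edge)
#' retention is uniform.
#'
#' @param partners character vector of the parent's neighbours.
#' @param betweenness ancestral edge betweenness of the parental edges, in
#'   the order of `partners`; nonnegative.
#' @param alpha reservation rate in `[0, 1]`.
#' @return character vector of retained partners.
#' @export
retain_edges <- function(partners, betweenness, alpha) {
  d_p <- length(partners)
  if (d_p < 1) stop("parent has no edges")
  if (length(betweenness) != d_p) stop("one betweenness value per partner required")
  if (any(betweenness < 0)) stop("negative edge betweenness")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  m <- min(max(round_half_up(alpha * d_p), 0), d_p)
  if (m == 0) return(character(0))
  if (m == d_p) return(partners)
  tot <- sum(betweenness)
  w <- if (tot > 0) 1 - betweenness / tot else rep(1, d_p)
  if (all(w <= 0)) w <- rep(1, d_p)
  partners[sample.int(d_p, m, replace = FALSE, prob = w)]
}

# weighted draw of `m` distinct items with weight ks*d (or d only);
# zero-weight candidates are never drawn
draw_partners <- function(candidates, weights, m, allow_shortfall = FALSE) {
  pos <- weights > 0
  n_pos <- sum(pos)
  if (m <= 0) return(character(0))
  if (n_pos < m) {
    if (!allow_shortfall) {
      stop("only ", n_pos, " positive-weight candidates for ", m, " draws")
    }
    return(candidates[pos])
  }
  candidates[pos][sample.int(n_pos, m, replace = FALSE,
                             prob = weights[pos])]
}

#' Choose rewiring partners for a duplicate gene
#'
#' After edge loss, a duplicate forms `round(<d_old> * beta)` new links.
#' Partners are drawn without replacement from the ancestral genes that are
#' neither the parent nor parental neighbours, with probability
#' proportional to `coreness * degree` — joint rich-gets-richer in degree
#' and depth.
#'
#' @param snapshot a [network_snapshot()].
#' @param parent parent gene id (it and its neighbours are excluded).
#' @param beta rewiring rate; `m` overrides the derived count when given.
#' @param m optional explicit partner count.
#' @param allow_shortfall if there are fewer positive-weight candidates than
#'   requested, return them all instead of erroring (default FALSE).
#' @return character vector of partner gene ids.
#' @export
rewire_targets <- function(snapshot, parent, beta, m = NULL,
                           allow_shortfall = FALSE) {
  if (is.null(m)) m <- round_half_up(snapshot$mean_degree * beta)
  excl <- c(parent, snapshot$neighbours[[parent]])
  cand <- setdiff(snapshot$genes, excl)
  w <- snapshot$coreness[cand] * snapshot$degree[cand]
  draw_partners(cand, w, m, allow_shortfall)
}

#' Choose partners for a de novo gene
#'
#' A de novo gene wires into the ancestral network until its degree reaches
#' `round(<d_old> * gamma)`; partners are drawn without replacement over all
#' ancestral genes with probability proportional to `coreness * degree`.
#'
#' @param snapshot a [network_snapshot()].
#' @param gamma connection rate; `m` overrides the derived count when given.
#' @param m optional explicit partner count.
#' @param allow_shortfall as in [rewire_targets()].
#' @return character vector of partner gene ids.
#' @export
attach_de_novo <- function(snapshot, gamma, m = NULL, allow_shortfall = FALSE) {
  if (!length(snapshot$genes)) stop("empty ancestral network")
  if (is.null(m)) m <- round_half_up(snapshot$mean_degree * gamma)
  w <- snapshot$coreness * snapshot$degree
  draw_partners(snapshot$genes, w, m, allow_shortfall)
}

# shared machinery: run n_dup duplications + n_novo de novo additions
# against a frozen snapshot. `model` is "improved" or "traditional".
evolve_step_core <- function(old_net, n_dup, n_novo, params, seed,
                             model = c("improved", "traditional"),
                             step_label = 1L, name_prefix = NULL,
                             allow_shortfall = FALSE) {
  model <- match.arg(model)
  stopifnot(n_dup >= 0, n_novo >= 0)
  snap <- network_snapshot(old_net, edge_betweenness = model == "improved")
  if (is.null(name_prefix)) name_prefix <- sprintf("s%s", step_label)

  old_rng <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_rng)) assign(".Random.seed", old_rng, envir = globalenv())
  }, add = TRUE)

  events <- vector("list", n_dup + n_novo)
  new_edges_a <- character(0)
  new_edges_b <- character(0)
  ev_i <- 0L

  add_edges <- function(child, partners) {
    if (length(partners)) {
      new_edges_a <<- c(new_edges_a, rep(child, length(partners)))
      new_edges_b <<- c(new_edges_b, partners)
    }
  }

  if (n_dup > 0) {
    for (i in seq_len(n_dup)) {
      set.seed(event_seed(seed, i))
      child <- sprintf("%s_dup%d", name_prefix, i)
      parent <- select_parent(snap)
      pn <- snap$neighbours[[parent]]
      d_p <- length(pn)
      if (model == "improved") {
        if (d_p > 0) {
          b <- snap$edge_betweenness[edge_key(parent, pn)]
          kept <- retain_edges(pn, unname(b), params$alpha)
        } else kept <- character(0)
        rew <- rewire_targets(snap, parent, params$beta,
                              allow_shortfall = allow_shortfall)
      } else {
        kept <- if (d_p > 0) pn[stats::runif(d_p) >= params$delta] else character(0)
        m_r <- round_half_up(snap$mean_degree * params$beta)
        cand <- setdiff(snap$genes, c(parent, pn))
        rew <- draw_partners(cand, snap$degree[cand], m_r, allow_shortfall)
      }
      add_edges(child, c(kept, rew))
      ev_i <- ev_i + 1L
      events[[ev_i]] <- data.frame(
        step = step_label, type = "duplication", child = child,
        parent = parent, parent_degree = d_p,
        n_retained = length(kept), n_rewired = length(rew),
        retained = paste(kept, collapse = ";"),
        deleted = paste(setdiff(pn, kept), collapse = ";"),
        rewired = paste(rew, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (n_novo > 0) {
    for (j in seq_len(n_novo)) {
      set.seed(event_seed(seed, n_dup + j))
      child <- sprintf("%s_novo%d", name_prefix, j)
      partners <- attach_de_novo(snap, params$gamma,
                                 allow_shortfall = allow_shortfall)
      add_edges(child, partners)
      ev_i <- ev_i + 1L
      events[[ev_i]] <- data.frame(
        step = step_label, type = "de_novo", child = child,
        parent = NA_character_, parent_degree = NA_integer_,
        n_retained = NA_integer_, n_rewired = length(partners),
        retained = "", deleted = "",
        rewired = paste(partners, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }

  new_net <- igraph::add_vertices(
    old_net, n_dup + n_novo,
    name = c(if (n_dup > 0) sprintf("%s_dup%d", name_prefix, seq_len(n_dup)),
             if (n_novo > 0) sprintf("%s_novo%d", name_prefix, seq_len(n_novo))))
  if (length(new_edges_a)) {
    new_net <- igraph::add_edges(
      new_net, rbind(match(new_edges_a, igraph::V(new_net)$name),
                     match(new_edges_b, igraph::V(new_net)$name)))
  }
  # annotate the additions
  nb <- igraph::vertex_attr(new_net, "new_branch")
  mech <- igraph::vertex_attr(new_net, "mechanism") %||%
    rep(NA_character_, igraph::vcount(new_net))
  par_attr <- igraph::vertex_attr(new_net, "parent") %||%
    rep(NA_character_, igraph::vcount(new_net))
  log_df <- do.call(rbind, events[seq_len(ev_i)]) %||%
    data.frame(step = integer(0), type = character(0), child = character(0))
  if (nrow(log_df)) {
    idx <- match(log_df$child, igraph::V(new_net)$name)
    mech[idx] <- ifelse(log_df$type == "duplication", "duplication", "de_novo")
    par_attr[idx] <- log_df$parent
    if (!is.null(nb)) nb[idx] <- step_label
  }
  new_net <- igraph::set_vertex_attr(new_net, "mechanism", value = mech)
  new_net <- igraph::set_vertex_attr(new_net, "parent", value = par_attr)
  if (!is.null(nb)) new_net <- igraph::set_vertex_attr(new_net, "new_branch", value = nb)
  class(new_net) <- unique(c("coexpression_network", class(new_net)))
  list(network = new_net, events = log_df, snapshot = snap)
}

#' One growth step of the improved model with known gene counts (model 1)
#'
#' Adds `n_dup` duplicate genes and `n_novo` de novo genes to the ancestral
#' network. All sampling statistics (degrees, coreness, edge betweenness,
#' mean degree) are frozen from the ancestral network; every event is
#' wired against that snapshot, so new genes never link to other new genes
#' within a step. Duplicates draw a uniform parent, keep
#' `round(alpha * d_p)` parental edges by betweenness-weighted retention,
#' and rewire `round(<d> * beta)` partners by coreness-times-degree
#' preferential attachment; de novo genes attach `round(<d> * gamma)`
#' partners the same way.
#'
#' @param old_net ancestral coexpression network.
#' @param n_dup,n_novo numbers of duplicate and de novo genes to add.
#' @param params an [evolution_params()].
#' @param seed integer seed; every event derives its own substream from it.
#' @param step_label integer tag recorded in the event log and in the
#'   `new_branch` annotation of added genes.
#' @param allow_shortfall tolerate fewer positive-weight partners than the
#'   target count (default FALSE).
#' @return list with `network` (the grown network), `events` (event-log
#'   data frame) and `snapshot` (the frozen [network_snapshot()]).
#' @export
evolve_step_model1 <- function(old_net, n_dup, n_novo, params, seed,
                               step_label = 1L, allow_shortfall = FALSE) {
  evolve_step_core(old_net, n_dup, n_novo, params, seed, model = "improved",
                   step_label = step_label, allow_shortfall = allow_shortfall)
}

#' One growth step of the improved model with known duration (model 2)
#'
#' As [evolve_step_model1()], but the gene counts are derived from the
#' step duration: `n_dup = round(r_dup * t)`, `n_novo = round(r_novo * t)`
#' (half-up), with the rates taken from `params`.
#'
#' @param old_net ancestral coexpression network.
#' @param t step duration in Myr (> 0).
#' @param params an [evolution_params()] carrying `r_dup` and `r_novo`.
#' @param seed integer seed.
#' @param step_label integer tag for logs and annotations.
#' @param allow_shortfall as in [evolve_step_model1()].
#' @return as [evolve_step_model1()], plus `n_dup`, `n_novo`.
#' @export
evolve_step_model2 <- function(old_net, t, params, seed, step_label = 1L,
                               allow_shortfall = FALSE) {
  if (t <= 0) stop("duration must be positive")
  n_dup <- round_half_up(params$r_dup * t)
  n_novo <- round_half_up(params$r_novo * t)
  out <- evolve_step_core(old_net, n_dup, n_novo, params, seed,
                          model = "improved", step_label = step_label,
                          allow_shortfall = allow_shortfall)
  out$n_dup <- n_dup
  out$n_novo <- n_novo
  out
}

#' One growth step of the traditional duplication-only baseline
#'
#' All `n` additions are duplicates: uniform parent, each inherited edge
#' independently removed with probability `delta`, and `round(<d> * beta)`
#' rewired partners drawn by degree-only preferential attachment.
#'
#' @param old_net ancestral coexpression network.
#' @param n number of duplicate genes to add.
#' @param params an [evolution_params()] (uses `delta` and `beta`).
#' @param seed integer seed.
#' @param step_label integer tag for logs and annotations.
#' @param allow_shortfall as in [evolve_step_model1()].
#' @return as [evolve_step_model1()].
#' @export
evolve_traditional <- function(old_net, n, params, seed, step_label = 1L,
                               allow_shortfall = FALSE) {
  evolve_step_core(old_net, n, 0L, params, seed, model = "traditional",
                   step_label = step_label, allow_shortfall = allow_shortfall)
}

#' Run a multi-step evolution
#'
#' Chains growth steps, re-freezing the snapshot between steps: each step's
#' output network is the next step's ancestral network. The schedule gives
#' one entry per step — `(n_dup, n_novo)` pairs for model 1, durations `t`
#' (Myr) for model 2, or total counts `n` for the traditional baseline.
#'
#' @param seed_net the starting (ancestral) network.
#' @param schedule for `model = "model1"`: a list of `c(n_dup, n_novo)` (or
#'   a 2-column matrix/data frame); for `"model2"`: numeric durations; for
#'   `"traditional"`: numeric counts.
#' @param params an [evolution_params()].
#' @param model `"model1"`, `"model2"` or `"traditional"`.
#' @param seed integer seed; step k uses substream `seed + k`.
#' @param topology compute a [topology_summary()] per network (default
#'   TRUE).
#' @param allow_shortfall as in [evolve_step_model1()].
#' @return list of class `evolution_run`: `series` (networks, seed first),
#'   `events` (combined event log), `summaries` (per-network topology
#'   summaries, or NULL), `model`, `params`, `seed`.
#' @export
run_evolution <- function(seed_net, schedule, params = evolution_params(),
                          model = c("model1", "model2", "traditional"),
                          seed = 1L, topology = TRUE, allow_shortfall = FALSE) {
  model <- match.arg(model)
  if (is.matrix(schedule) || is.data.frame(schedule)) {
    schedule <- lapply(seq_len(nrow(schedule)), function(i) as.numeric(schedule[i, ]))
  }
  if (!length(schedule)) stop("schedule is empty")
  series <- vector("list", length(schedule) + 1L)
  series[[1L]] <- seed_net
  logs <- vector("list", length(schedule))
  net <- seed_net
  for (k in seq_along(schedule)) {
    step_seed <- event_seed(seed, 7919L * k)
    res <- switch(model,
      model1 = {
        sk <- schedule[[k]]
        evolve_step_model1(net, sk[1], sk[2], params, step_seed,
                           step_label = k, allow_shortfall = allow_shortfall)
      },
      model2 = evolve_step_model2(net, schedule[[k]], params, step_seed,
                                  step_label = k,
                                  allow_shortfall = allow_shortfall),
      traditional = evolve_traditional(net, schedule[[k]], params, step_seed,
                                       step_label = k,
                                       allow_shortfall = allow_shortfall))
    net <- res$network
    series[[k + 1L]] <- net
    logs[[k]] <- res$events
  }
  structure(list(
    series = series,
    events = do.call(rbind, logs),
    summaries = if (topology) lapply(series, topology_summary) else NULL,
    model = model, params = params, seed = seed
  ), class = "evolution_run")
}

#' @export
print.evolution_run <- function(x, ...) {
  sizes <- vapply(x$series, igraph::vcount, numeric(1))
  cat(sprintf("evolution run (%s, seed %d): %d steps\n",
              x$model, x$seed, length(x$series) - 1L))
  cat("  node counts:", paste(sizes, collapse = " -> "), "\n")
  invisible(x)
}
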