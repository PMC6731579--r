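#' Edge reservation rate of a duplication event
#'
#' The fraction of parental edges a duplicate gene ultimately keeps:
#' alpha = d_pub / d_p, where d_p is the parent's degree in the ancestral
#' network and d_pub the number of parental partners the child retains.
#'
#' @param retained_count number of retained parental edges (d_pub).
#' @param parent_degree parent degree in the ancestral network (d_p >= 1).
#' @return fraction in `[0, 1]`.
#' @export
reservation_rate <- function(retained_count, parent_degree) {
  if (any(parent_degree < 1)) stop("parent with no edges cannot be evaluated")
  if (any(retained_count > parent_degree)) stop("retained count exceeds parent degree")
  retained_count / parent_degree
}

#' Rewiring rate of a duplication event
#'
#' The number of brand-new partners a duplicate gene acquires, expressed as
#' a fraction of the ancestral network's mean degree: beta = n_re / <d>.
#'
#' @param n_rewired number of rewired (non-parental) partners.
#' @param old_mean_degree mean degree of the ancestral network (> 0).
#' @return nonnegative fraction (can exceed 1).
#' @export
rewiring_rate <- function(n_rewired, old_mean_degree) {
  if (any(old_mean_degree <= 0)) stop("ancestral mean degree must be positive")
  n_rewired / old_mean_degree
}

#' Connection rate of a de novo gene
#'
#' A de novo gene's degree as a fraction of the ancestral network's mean
#' degree: zeta = d_novo / <d>.
#'
#' @param novo_degree degree of the de novo gene into the ancestral network.
#' @param old_mean_degree mean degree of the ancestral network (> 0).
#' @return nonnegative fraction.
#' @export
connection_rate <- function(novo_degree, old_mean_degree) {
  if (any(old_mean_degree <= 0)) stop("ancestral mean degree must be positive")
  novo_degree / old_mean_degree
}

#' Extract duplication and de novo wiring events between two networks
#'
#' Given an ancestral network and its successor (the successor contains
#' every ancestral gene plus the newly added ones), reconstructs per new
#' gene what happened: for duplicates, which parental edges were retained
#' or lost and which partners were newly rewired; for de novo genes, their
#' degree into the ancestral network.
#'
#' Parentage comes from a `parent` annotation when available; otherwise the
#' parent is inferred as the ancestral gene with maximal Jaccard overlap
#' between its ancestral neighbourhood and the child's ancestral
#' neighbourhood (ties broken by lexicographic gene id), and the event is
#' flagged `parent_inferred`.
#'
#' @param old_net,new_net consecutive coexpression networks.
#' @param annotations data frame with columns `gene`, `mechanism`
#'   (`"duplication"`/`"de_novo"`) and optionally `parent`, covering the
#'   genes added in `new_net`. Defaults to `new_net`'s vertex annotations.
#' @param edge_betweenness optional named vector of ancestral edge
#'   betweenness (names `"a|b"`, see [topology_summary()]); computed from
#'   `old_net` when NULL and a duplication event exists.
#' @return list of class `wiring_events`: `duplications` (data frame, one
#'   row per duplicate: child, parent, parent_degree, retained_count,
#'   n_rewired, alpha, beta, parent_inferred, plus `;`-joined `retained`,
#'   `deleted`, `rewired` partner lists and mean betweenness of retained and
#'   deleted parental edges), `de_novo` (child, degree, zeta),
#'   `old_mean_degree`.
#' @export
extract_events <- function(old_net, new_net, annotations = NULL,
                           edge_betweenness = NULL) {
  old_genes <- igraph::V(old_net)$name
  new_genes <- igraph::V(new_net)$name
  if (!all(old_genes %in% new_genes)) {
    stop("new_net must contain every ancestral gene")
  }
  added <- setdiff(new_genes, old_genes)
  ann <- if (is.null(annotations)) network_annotations(new_net) else as.data.frame(annotations)
  if (!"mechanism" %in% names(ann)) stop("annotations need a 'mechanism' column")
  ann <- ann[ann$gene %in% added, , drop = FALSE]
  missing_mech <- setdiff(added, ann$gene[!is.na(ann$mechanism)])
  if (length(missing_mech)) {
    stop("added genes without a mechanism annotation: ",
         paste(utils::head(missing_mech, 10), collapse = ", "))
  }
  old_mean_degree <- mean(igraph::degree(old_net))
  old_nbrs <- lapply(igraph::adjacent_vertices(old_net, igraph::V(old_net)),
                     function(v) igraph::V(old_net)$name[as.integer(v)])
  names(old_nbrs) <- old_genes

  child_old_nbrs <- function(child) {
    nb <- igraph::V(new_net)$name[
      as.integer(igraph::neighbors(new_net, child))]
    intersect(nb, old_genes)
  }

  dup_genes <- ann$gene[ann$mechanism == "duplication"]
  novo_genes <- ann$gene[ann$mechanism == "de_novo"]

  eb <- edge_betweenness
  if (is.null(eb) && length(dup_genes)) {
    if (igraph::ecount(old_net) > 0) {
      ebv <- igraph::edge_betweenness(old_net, directed = FALSE)
      el <- igraph::as_edgelist(old_net, names = TRUE)
      eb <- stats::setNames(ebv, edge_key(el[, 1], el[, 2]))
    } else {
      eb <- numeric(0)
    }
  }

  dup_rows <- lapply(dup_genes, function(child) {
    nbrs <- child_old_nbrs(child)
    parent <- NA_character_
    if ("parent" %in% names(ann)) {
      p <- ann$parent[ann$gene == child]
      if (length(p) == 1 && !is.na(p) && nzchar(p)) parent <- p
    }
    inferred <- FALSE
    if (is.na(parent)) {
      jac <- vapply(old_genes, function(g) {
        u <- length(union(old_nbrs[[g]], nbrs))
        if (u == 0) 0 else length(intersect(old_nbrs[[g]], nbrs)) / u
      }, numeric(1))
      parent <- sort(old_genes[jac == max(jac)])[1]
      inferred <- TRUE
    }
    if (!parent %in% old_genes) stop("parent ", parent, " not in ancestral network")
    pn <- old_nbrs[[parent]]
    retained <- intersect(nbrs, pn)
    deleted <- setdiff(pn, retained)
    rewired <- setdiff(setdiff(nbrs, pn), parent)
    d_p <- length(pn)
    mean_b <- function(partners) {
      if (!length(partners) || !length(eb)) return(NA_real_)
      mean(eb[edge_key(parent, partners)], na.rm = TRUE)
    }
    data.frame(
      child = child, parent = parent, parent_degree = d_p,
      retained_count = length(retained), n_rewired = length(rewired),
      alpha = if (d_p > 0) length(retained) / d_p else NA_real_,
      beta = length(rewired) / old_mean_degree,
      parent_inferred = inferred,
      retained = paste(retained, collapse = ";"),
      deleted = paste(deleted, collapse = ";"),
      rewired = paste(rewired, collapse = ";"),
      retained_betweenness = mean_b(retained),
      deleted_betweenness = mean_b(deleted),
      stringsAsFactors = FALSE)
  })
  novo_rows <- lapply(novo_genes, function(child) {
    d <- length(child_old_nbrs(child))
    data.frame(child = child, degree = d, zeta = d / old_mean_degree,
               stringsAsFactors = FALSE)
  })
  structure(list(
    duplications = do.call(rbind, dup_rows) %||%
      data.frame(child = character(0)),
    de_novo = do.call(rbind, novo_rows) %||%
      data.frame(child = character(0)),
    old_mean_degree = old_mean_degree
  ), class = "wiring_events")
}

#' Estimate evolution parameters from an age-stratified network series
#'
#' Walks consecutive network pairs, extracts wiring events, and averages:
#' each transition contributes its mean per-event alpha, beta and zeta, and
#' the overall parameter is the unweighted mean of the per-transition means
#' (transitions with no event of a class are excluded from that class's
#' average). delta, the edge-removal probability of the duplication-only
#' baseline, is reported as 1 - alpha.
#'
#' @param series list of coexpression networks, ancestral first.
#' @param annotations optional annotation data frame passed to
#'   [extract_events()] (defaults to each network's vertex annotations).
#' @return list of class `evolution_params`: `alpha`, `beta`, `gamma`,
#'   `delta`, and `per_network` (per-transition means).
#' @export
estimate_evolution_params <- function(series, annotations = NULL) {
  if (length(series) < 2) stop("need at least two networks")
  rows <- lapply(seq_len(length(series) - 1L), function(i) {
    ev <- extract_events(series[[i]], series[[i + 1L]], annotations)
    data.frame(
      transition = i,
      n_dup = nrow(ev$duplications), n_novo = nrow(ev$de_novo),
      alpha = if (nrow(ev$duplications)) mean(ev$duplications$alpha) else NA_real_,
      beta = if (nrow(ev$duplications)) mean(ev$duplications$beta) else NA_real_,
      zeta = if (nrow(ev$de_novo)) mean(ev$de_novo$zeta) else NA_real_)
  })
  per <- do.call(rbind, rows)
  alpha <- mean(per$alpha, na.rm = TRUE)
  structure(list(
    alpha = alpha,
    beta = mean(per$beta, na.rm = TRUE),
    gamma = mean(per$zeta, na.rm = TRUE),
    delta = 1 - alpha,
    per_network = per
  ), class = "evolution_params")
}

#' @export
print.evolution_params <- function(x, ...) {
  cat(sprintf(
    "evolution parameters: alpha %.4f, beta %.4f, gamma %.4f, delta %.4f\n",
    x$alpha, x$beta, x$gamma, x$delta))
  invisible(x)
}

#' Randomness diagnostics for parent-gene selection
#'
#' If duplication picks parents uniformly at random, parents' mean degree
#' and coreness should fluctuate around the ancestral network's means, and
#' about half of parents should sit above the network median. Reports both
#' the mean comparison and the above-median / above-mean fractions for
#' degree and coreness.
#'
#' @param events a [extract_events()] result (or a data frame with a
#'   `parent` column).
#' @param old_net the ancestral network the parents were drawn from.
#' @return data frame with one row per metric (`degree`, `coreness`):
#'   parent mean, network mean, network median, fraction of parents above
#'   the network median and above the network mean.
#' @export
randomness_diagnostics <- function(events, old_net) {
  parents <- if (is.data.frame(events)) events$parent else events$duplications$parent
  if (!length(parents)) stop("no duplication events")
  deg <- igraph::degree(old_net)
  names(deg) <- igraph::V(old_net)$name
  ks <- kshell_decomposition(old_net)
  row_for <- function(metric, v) {
    pv <- v[parents]
    data.frame(metric = metric,
               parent_mean = mean(pv), network_mean = mean(v),
               network_median = stats::median(v),
               frac_above_median = mean(pv > stats::median(v)),
               frac_above_mean = mean(pv > mean(v)))
  }
  rbind(row_for("degree", deg), row_for("coreness", ks))
}

#' Betweenness of retained vs deleted parental edges
#'
#' Duplicate genes tend to keep parental edges of low edge betweenness and
#' lose the high-betweenness ones. Aggregates, over all duplication events
#' with both retained and deleted edges, the mean ancestral edge betweenness
#' of each class.
#'
#' @param events a [extract_events()] result.
#' @return list with `per_event` (child, retained/deleted mean betweenness)
#'   and aggregate `retained_mean`, `deleted_mean`, `ratio`
#'   (retained / deleted).
#' @export
betweenness_retention_report <- function(events) {
  d <- events$duplications
  if (!nrow(d)) stop("no duplication events")
  per <- d[, c("child", "retained_betweenness", "deleted_betweenness")]
  rm_ <- mean(d$retained_betweenness, na.rm = TRUE)
  dm <- mean(d$deleted_betweenness, na.rm = TRUE)
  list(per_event = per, retained_mean = rm_, deleted_mean = dm,
       ratio = rm_ / dm)
}
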