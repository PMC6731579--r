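#' Relative error of a simulated topological property
#'
#' sigma = |A - a| / A x 100, where `A` is the reference (real) value and
#' `a` the simulated one.
#'
#' @param A reference value (nonzero).
#' @param a simulated value.
#' @return percentage (nonnegative).
#' @export
relative_error <- function(A, a) {
  if (any(A == 0)) stop("reference value must be nonzero")
  abs(A - a) / abs(A) * 100
}

# the five properties compared across simulated and reference networks
EVAL_METRICS <- c("avg_degree", "transitivity", "avg_pathlength",
                  "avg_node_betweenness", "avg_edge_betweenness")

metric_value <- function(ts, metric, transitivity_type = c("global", "local")) {
  transitivity_type <- match.arg(transitivity_type)
  if (metric == "transitivity") {
    if (transitivity_type == "global") ts$global_transitivity else ts$avg_clustering
  } else {
    ts[[metric]]
  }
}

#' Compare a simulated network series against a reference series
#'
#' Computes, per evolutionary step and per topological property (average
#' degree, transitivity, path length, node betweenness, edge betweenness),
#' the relative error sigma of the simulated value against the reference,
#' plus the mean sigma per property across steps. The seed networks
#' (first series entries) are excluded when `skip_first = TRUE` since both
#' series start from the same ancestral network.
#'
#' @param simulated,reference equal-length lists of coexpression networks,
#'   or of [topology_summary()] objects.
#' @param metrics character vector of properties to compare.
#' @param transitivity_type `"global"` (transitivity) or `"local"` (mean
#'   local clustering) for the `transitivity` panel.
#' @param skip_first drop the first (seed) entry from the comparison.
#' @return list of class `comparison_report`: `per_step` (step, metric,
#'   reference, simulated, sigma) and `mean_sigma` (named by metric).
#' @export
compare_series <- function(simulated, reference, metrics = EVAL_METRICS,
                           transitivity_type = c("global", "local"),
                           skip_first = TRUE) {
  transitivity_type <- match.arg(transitivity_type)
  if (length(simulated) != length(reference)) {
    stop("series length mismatch: ", length(simulated), " vs ", length(reference))
  }
  as_summary <- function(x) {
    if (inherits(x, "topology_summary")) x else topology_summary(x)
  }
  sim <- lapply(simulated, as_summary)
  ref <- lapply(reference, as_summary)
  steps <- seq_along(sim)
  if (skip_first && length(steps) > 1) steps <- steps[-1]
  rows <- list()
  for (s in steps) {
    for (m in metrics) {
      A <- metric_value(ref[[s]], m, transitivity_type)
      a <- metric_value(sim[[s]], m, transitivity_type)
      rows[[length(rows) + 1L]] <- data.frame(
        step = s - 1L, metric = m, reference = A, simulated = a,
        sigma = if (A != 0) relative_error(A, a) else NA_real_)
    }
  }
  per_step <- do.call(rbind, rows)
  mean_sigma <- vapply(split(per_step$sigma, per_step$metric), mean,
                       numeric(1), na.rm = TRUE)[metrics]
  structure(list(per_step = per_step, mean_sigma = mean_sigma),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("mean relative error (%) by property:\n")
  for (m in names(x$mean_sigma)) {
    cat(sprintf("  %-22s %.2f\n", m, x$mean_sigma[m]))
  }
  invisible(x)
}

# replicate-averaged metrics of the first evolved step under model 2
replicate_step_metrics <- function(seed_net, params, t, replicates, seed,
                                   metrics, transitivity_type) {
  vals <- matrix(NA_real_, nrow = replicates, ncol = length(metrics),
                 dimnames = list(NULL, metrics))
  for (r in seq_len(replicates)) {
    res <- evolve_step_model2(seed_net, t, params, seed + r - 1L)
    ts <- topology_summary(res$network)
    vals[r, ] <- vapply(metrics,
                        function(m) metric_value(ts, m, transitivity_type),
                        numeric(1))
  }
  colMeans(vals)
}

#' Sensitivity of simulated topology to the evolution parameters
#'
#' Perturbs one parameter F by a relative change (default +20%), re-runs
#' the first evolutionary step, and reports the sensitivity coefficient
#' S = (dA/A) / (dF/F) for each topological property A. Both baseline and
#' perturbed property values are replicate means (stochastic simulation).
#' The step is run under the duration-driven model so that the generation
#' rates `r_dup` and `r_novo` are perturbable alongside `alpha`, `beta`
#' and `gamma`.
#'
#' @param seed_net ancestral network.
#' @param params baseline [evolution_params()].
#' @param param one of `"r_dup"`, `"alpha"`, `"beta"`, `"r_novo"`,
#'   `"gamma"`.
#' @param rel_change relative perturbation dF/F (default 0.2; may be
#'   negative).
#' @param t step duration in Myr (default 65.05, the first branch
#'   transition).
#' @param metrics properties to evaluate.
#' @param transitivity_type as in [compare_series()].
#' @param replicates replicate simulations per condition (default 10).
#' @param seed integer seed (replicate r uses seed + r - 1).
#' @return data frame of class `sensitivity_report`: parameter, baseline
#'   and perturbed parameter values, per metric the baseline/perturbed
#'   property values and S.
#' @export
sensitivity <- function(seed_net, params, param, rel_change = 0.2,
                        t = 65.05, metrics = EVAL_METRICS,
                        transitivity_type = c("global", "local"),
                        replicates = 10, seed = 1L) {
  transitivity_type <- match.arg(transitivity_type)
  if (!param %in% c("r_dup", "alpha", "beta", "r_novo", "gamma")) {
    stop("unknown parameter: ", param)
  }
  if (rel_change == 0) stop("relative change must be nonzero")
  F0 <- params[[param]]
  if (F0 == 0) stop("baseline parameter value is zero")
  pert <- params
  pert[[param]] <- F0 * (1 + rel_change)
  if (param == "alpha") pert$delta <- 1 - pert$alpha
  pert <- do.call(evolution_params,
                  pert[c("alpha", "beta", "gamma", "delta", "r_dup", "r_novo")])
  base_A <- replicate_step_metrics(seed_net, params, t, replicates, seed,
                                   metrics, transitivity_type)
  pert_A <- replicate_step_metrics(seed_net, pert, t, replicates,
                                   seed + replicates, metrics,
                                   transitivity_type)
  if (any(base_A == 0)) stop("baseline property value is zero")
  S <- ((pert_A - base_A) / base_A) / rel_change
  out <- data.frame(parameter = param, baseline_F = F0,
                    perturbed_F = F0 * (1 + rel_change),
                    metric = metrics, baseline_A = unname(base_A),
                    perturbed_A = unname(pert_A), S = unname(S))
  class(out) <- c("sensitivity_report", "data.frame")
  out
}

#' Topological trajectory of a gene cohort across a network series
#'
#' Tracks, per network of the series, the mean degree, local clustering,
#' path length, and node betweenness of a fixed set of genes, plus the mean
#' betweenness of edges incident to the cohort. Path length is the mean
#' shortest-path length over connected pairs with at least one endpoint in
#' the cohort.
#'
#' @param series list of coexpression networks.
#' @param cohort character vector of gene ids; networks that do not contain
#'   the full cohort are reported as `NA` rows.
#' @return data frame, one row per series entry: step, cohort size present,
#'   `mean_degree`, `mean_clustering`, `mean_pathlength`,
#'   `mean_node_betweenness`, `mean_incident_edge_betweenness`.
#' @export
cohort_trajectory <- function(series, cohort) {
  if (!length(cohort)) stop("empty cohort")
  rows <- lapply(seq_along(series), function(k) {
    net <- series[[k]]
    present <- intersect(cohort, igraph::V(net)$name)
    if (!length(present)) {
      return(data.frame(step = k - 1L, n_present = 0L, mean_degree = NA_real_,
                        mean_clustering = NA_real_, mean_pathlength = NA_real_,
                        mean_node_betweenness = NA_real_,
                        mean_incident_edge_betweenness = NA_real_))
    }
    ts <- topology_summary(net)
    dists <- igraph::distances(net, v = present)
    dists[dists == 0] <- NA  # self-pairs
    finite <- dists[is.finite(dists)]
    inc <- igraph::incident_edges(net, present)
    inc_ids <- unique(unlist(lapply(inc, as.integer)))
    inc_b <- if (length(inc_ids)) {
      el <- igraph::as_edgelist(net, names = TRUE)[inc_ids, , drop = FALSE]
      mean(ts$edge_betweenness[edge_key(el[, 1], el[, 2])])
    } else NA_real_
    data.frame(
      step = k - 1L, n_present = length(present),
      mean_degree = mean(ts$degree[present]),
      mean_clustering = mean(ts$clustering[present]),
      mean_pathlength = if (length(finite)) mean(finite) else NA_real_,
      mean_node_betweenness = mean(ts$node_betweenness[present]),
      mean_incident_edge_betweenness = inc_b)
  })
  do.call(rbind, rows)
}
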