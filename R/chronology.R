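#' Branch timeline of gene ages
#'
#' A branch timeline records, per evolutionary age branch, the splitting
#' time (Myr before present, stored as positive numbers), the gene age
#' (midpoint of the branch's splitting time and the next one, with 0 after
#' the youngest branch), and the inter-branch time interval (difference of
#' consecutive gene ages).
#'
#' @param branch integer branch ids, oldest first.
#' @param splitting_time positive Myr, strictly decreasing toward the present.
#' @param n_genes optional gene counts per branch.
#' @return data frame of class `branch_timeline` with columns `branch`,
#'   `splitting_time`, `gene_age`, `interval` (interval is `NA` for the
#'   oldest branch) and optionally `n_genes`.
#' @export
branch_timeline <- function(branch, splitting_time, n_genes = NULL) {
  if (length(branch) != length(splitting_time)) stop("length mismatch")
  if (any(diff(splitting_time) >= 0)) {
    stop("splitting times must be strictly decreasing toward the present")
  }
  age <- (splitting_time + c(splitting_time[-1], 0)) / 2
  interval <- c(NA_real_, -diff(age))
  out <- data.frame(branch = as.integer(branch),
                    splitting_time = splitting_time,
                    gene_age = age, interval = interval)
  if (!is.null(n_genes)) out$n_genes <- as.integer(n_genes)
  class(out) <- c("branch_timeline", "data.frame")
  out
}

#' Default 14-branch human gene-age timeline
#'
#' The human lineage divided into 14 age branches (0 = oldest), with per-
#' branch splitting times in Myr and the number of network genes assigned to
#' each branch in the reference human coexpression network.
#'
#' @return a [branch_timeline()] with 14 rows.
#' @export
default_branch_timeline <- function() {
  branch_timeline(
    branch = 0:13,
    splitting_time = c(454.6, 361.2, 324.5, 220.2, 176.1, 104.7, 97.4,
                       91, 44.2, 29.6, 18.8, 15.1, 6.1, 0),
    n_genes = c(6541, 780, 168, 210, 142, 129, 16, 6, 20, 10, 9, 11, 11, 8)
  )
}

#' Default per-branch counts of newly added genes by origination mechanism
#'
#' Gene counts for the repartitioned branches 1-6 of the reference human
#' coexpression network, split into duplication and de novo origins.
#'
#' @return data frame with columns `new_branch`, `n_new`, `n_dup`, `n_novo`.
#' @export
default_generation_counts <- function() {
  data.frame(
    new_branch = 1:6,
    n_new  = c(780, 168, 210, 271, 22, 69),
    n_dup  = c(708, 150, 185, 260, 22, 69),
    n_novo = c(72, 18, 25, 11, 0, 0)
  )
}

# merge map from the 14 original branches to the 7 repartitioned ones
REPARTITION_MAP <- c(0, 1, 2, 3, 4, 4, 5, 5, 6, 6, 6, 6, 6, 6)

#' Repartition 14 age branches into 7 near-uniform branches
#'
#' The fine 14-branch division has very uneven time intervals and tiny gene
#' counts in recent branches. Branches are merged as 0-3 kept, 4-5 -> 4,
#' 6-7 -> 5, 8-13 -> 6; each merged branch takes the splitting time of its
#' oldest member, and gene ages / intervals are recomputed with the midpoint
#' rule.
#'
#' @param timeline a 14-branch [branch_timeline()].
#' @return list with `timeline` (the 7-branch [branch_timeline()]) and
#'   `merge_map` (named integer vector, original branch -> new branch).
#' @export
repartition_branches <- function(timeline = default_branch_timeline()) {
  tl <- as.data.frame(timeline)
  if (nrow(tl) != 14L) stop("expected 14 original branches, got ", nrow(tl))
  map <- REPARTITION_MAP
  names(map) <- as.character(tl$branch)
  oldest <- !duplicated(map)
  new_tl <- branch_timeline(
    branch = unique(map),
    splitting_time = tl$splitting_time[oldest],
    n_genes = if ("n_genes" %in% names(tl)) {
      as.integer(tapply(tl$n_genes, map, sum)[as.character(unique(map))])
    } else NULL
  )
  list(timeline = new_tl, merge_map = map)
}

#' Map original branch ids to repartitioned branch ids
#'
#' @param branch integer vector of original branch ids (0-13).
#' @return integer vector of repartitioned branch ids (0-6).
#' @export
new_branch_of <- function(branch) {
  if (any(branch < 0 | branch > 13, na.rm = TRUE)) stop("branch ids must be 0-13")
  REPARTITION_MAP[branch + 1L]
}

#' Build the age-stratified network series
#'
#' Network k is the subgraph induced by all genes of repartitioned branches
#' 0..k, so the series grows monotonically from the ancestral network 0 to
#' the full present-day network.
#'
#' @param net a coexpression network whose vertices all carry a `new_branch`
#'   annotation (see [annotate_network()]).
#' @param n_branches number of growth steps (default 6, giving networks 0-6).
#' @return list of `n_branches + 1` coexpression networks.
#' @export
build_network_series <- function(net, n_branches = 6) {
  nb <- igraph::vertex_attr(net, "new_branch")
  if (is.null(nb) || anyNA(nb)) {
    offenders <- if (is.null(nb)) igraph::V(net)$name else igraph::V(net)$name[is.na(nb)]
    stop("genes without a new_branch annotation: ",
         paste(utils::head(offenders, 10), collapse = ", "),
         if (length(offenders) > 10) " ..." else "")
  }
  lapply(0:n_branches, function(k) {
    sub <- igraph::induced_subgraph(net, which(nb <= k))
    class(sub) <- unique(c("coexpression_network", class(sub)))
    sub
  })
}

#' Estimate per-Myr gene generation rates
#'
#' The generation rate of each gene class is the unweighted mean, over the
#' six branch transitions, of (genes added in the transition) / (transition
#' time interval in Myr) — a mean of ratios, not a ratio of sums.
#'
#' @param counts data frame with columns `new_branch` (1..k), `n_dup`,
#'   `n_novo` (and optionally `n_new`); see [default_generation_counts()].
#' @param timeline the repartitioned [branch_timeline()] (7 rows), or a
#'   numeric vector of the k transition intervals in Myr.
#' @return list of class `generation_rates` with `r_dup`, `r_novo`, `r_new`
#'   (genes/Myr) and the per-transition rate table `per_branch`.
#' @export
estimate_generation_rates <- function(counts = default_generation_counts(),
                                      timeline = repartition_branches()$timeline) {
  cts <- as.data.frame(counts)
  iv <- if (is.numeric(timeline)) timeline else as.data.frame(timeline)$interval[-1]
  if (length(iv) != nrow(cts)) {
    stop("need one time interval per branch transition (",
         nrow(cts), " transitions, ", length(iv), " intervals)")
  }
  if (any(iv <= 0)) stop("time intervals must be positive")
  n_new <- if ("n_new" %in% names(cts)) cts$n_new else cts$n_dup + cts$n_novo
  per <- data.frame(new_branch = cts$new_branch, interval = iv,
                    r_dup = cts$n_dup / iv, r_novo = cts$n_novo / iv,
                    r_new = n_new / iv)
  structure(list(r_dup = mean(per$r_dup), r_novo = mean(per$r_novo),
                 r_new = mean(per$r_new), per_branch = per),
            class = "generation_rates")
}

#' @export
print.generation_rates <- function(x, ...) {
  cat(sprintf("generation rates (genes/Myr): duplication %.2f, de novo %.2f, all new %.2f\n",
              x$r_dup, x$r_novo, x$r_new))
  invisible(x)
}
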