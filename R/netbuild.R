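#' Filter an expression matrix to a complete genes-by-tissues submatrix
#'
#' Raw expression tables typically have missing values in many tissues. This
#' selects a tissue subset of the requested size by greedy search — at each
#' step adding the tissue that keeps the number of genes with complete data
#' maximal — and then keeps only the genes observed in every selected tissue.
#'
#' @param expr numeric matrix, genes in rows (rownames = gene ids), tissues
#'   in columns (colnames = tissue ids); `NA` marks missing expression.
#' @param n_tissues number of tissues to retain (default 26).
#' @return the complete submatrix, genes x `n_tissues`.
#' @export
filter_expression <- function(expr, n_tissues = 26) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) rownames(expr) <- paste0("g", seq_len(nrow(expr)))
  if (is.null(colnames(expr))) colnames(expr) <- paste0("t", seq_len(ncol(expr)))
  if (n_tissues > ncol(expr)) {
    stop("requested ", n_tissues, " tissues but only ", ncol(expr), " available")
  }
  obs <- !is.na(expr)
  chosen <- integer(0)
  complete <- rep(TRUE, nrow(expr))
  for (step in seq_len(n_tissues)) {
    cand <- setdiff(seq_len(ncol(expr)), chosen)
    gains <- vapply(cand, function(j) sum(complete & obs[, j]), numeric(1))
    best <- cand[which.max(gains)]
    chosen <- c(chosen, best)
    complete <- complete & obs[, best]
  }
  if (!any(complete)) {
    # report the largest tissue subset that still keeps at least one gene
    feasible <- 0L
    keep <- rep(TRUE, nrow(expr))
    for (j in chosen) {
      if (!any(keep & obs[, j])) break
      keep <- keep & obs[, j]
      feasible <- feasible + 1L
    }
    stop("no gene has complete data across ", n_tissues,
         " tissues; largest feasible tissue count is ", feasible)
  }
  expr[complete, sort(chosen), drop = FALSE]
}

#' Build a coexpression network by Pearson-correlation thresholding
#'
#' Two genes are linked when the Pearson correlation of their expression
#' profiles across tissues exceeds `threshold` (signed correlation, strict
#' inequality; anti-correlated genes are never linked). Genes left with no
#' links are excluded from the returned network.
#'
#' @param expr complete numeric matrix, genes x tissues (>= 3 tissues).
#' @param threshold correlation threshold in (0, 1); default 0.7.
#' @param keep_isolated keep zero-degree genes as vertices (default FALSE).
#' @return a [coexpression_network()].
#' @export
build_network <- function(expr, threshold = 0.7, keep_isolated = FALSE) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3) stop("need at least 3 tissues for Pearson correlation")
  if (anyNA(expr)) stop("expression matrix must be complete; see filter_expression()")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (is.null(rownames(expr))) rownames(expr) <- paste0("g", seq_len(nrow(expr)))
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warning("constant expression (zero variance) for: ",
            paste(rownames(expr)[sds == 0], collapse = ", "),
            "; these genes form no edges")
  }
  cm <- suppressWarnings(stats::cor(t(expr)))
  cm[is.na(cm)] <- -Inf
  diag(cm) <- -Inf
  hit <- which(cm > threshold & upper.tri(cm), arr.ind = TRUE)
  edges <- data.frame(a = rownames(expr)[hit[, 1]], b = rownames(expr)[hit[, 2]])
  coexpression_network(edges,
                       nodes = if (keep_isolated) rownames(expr) else NULL)
}

#' Scale-free and hierarchy diagnostics
#'
#' Fits the log-log slope of the degree distribution (frequency of degree k
#' vs k over degrees with nonzero count) and of the degree-conditioned
#' clustering profile c(k), both by ordinary least squares on log10 scales.
#' A heavy-tailed network has a degree slope magnitude typically between 1
#' and 2 for biological networks, and a hierarchical one has a c(k) slope
#' near -1.
#'
#' @param net a coexpression network with at least 3 distinct degrees.
#' @return list of class `scale_free_diagnostics`: `degree_slope` (magnitude
#'   of the fitted degree-distribution slope), `ck_slope` (signed slope of
#'   c(k)), `n_nodes`, `n_edges`.
#' @export
scale_free_diagnostics <- function(net) {
  deg <- igraph::degree(net)
  tab <- table(deg[deg > 0])
  k <- as.numeric(names(tab))
  if (length(k) < 3) stop("need >= 3 distinct positive degrees to fit a slope")
  freq <- as.numeric(tab)
  fit_deg <- stats::lm(log10(freq) ~ log10(k))
  cc <- igraph::transitivity(net, type = "localundirected", isolates = "zero")
  ck <- tapply(cc[deg > 0], deg[deg > 0], mean)
  pos <- ck > 0
  ck_slope <- NA_real_
  if (sum(pos) >= 3) {
    kk <- as.numeric(names(ck))[pos]
    fit_ck <- stats::lm(log10(ck[pos]) ~ log10(kk))
    ck_slope <- unname(stats::coef(fit_ck)[2])
  }
  structure(list(
    degree_slope = abs(unname(stats::coef(fit_deg)[2])),
    ck_slope = ck_slope,
    n_nodes = igraph::vcount(net), n_edges = igraph::ecount(net)
  ), class = "scale_free_diagnostics")
}

#' @export
print.scale_free_diagnostics <- function(x, ...) {
  cat(sprintf("scale-free diagnostics: %d nodes, %d edges\n", x$n_nodes, x$n_edges))
  cat(sprintf("  degree-distribution slope magnitude: %.3f\n", x$degree_slope))
  cat(sprintf("  c(k) slope: %s\n",
              if (is.na(x$ck_slope)) "NA" else sprintf("%.3f", x$ck_slope)))
  invisible(x)
}
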