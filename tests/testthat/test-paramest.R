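test_that("the three per-event rate formulas and their guards", {
  expect_equal(reservation_rate(5, 10), 0.5)
  expect_equal(reservation_rate(0, 4), 0)
  expect_error(reservation_rate(1, 0), "no edges")
  expect_equal(rewiring_rate(6, 6), 1)
  expect_equal(rewiring_rate(0, 5), 0)
  expect_error(rewiring_rate(2, 0), "positive")
  expect_equal(connection_rate(8, 8), 1)
  expect_error(connection_rate(3, -1), "positive")
})

test_that("printed per-network rates average to the published parameters", {
  expect_equal(round(mean(c(4.83, 6.56, 10.45, 7.85, 5.90, 41.75)), 2), 12.89)
  expect_equal(round(mean(c(102.60, 58.72, 148.37, 80.61, 43.65, 44.66)), 2), 79.77)
  expect_lt(abs(mean(c(126.02, 78.03, 100.97, 92.12)) - 99.29), 0.005 + 1e-9)
  expect_equal(round(1 - 0.1289, 4), 0.8711)
})

test_that("event extraction does the documented set arithmetic", {
  # parent p with ancestral neighbours {a, b, c}; child keeps a, rewires to x
  old_net <- coexpression_network(
    data.frame(a = c("p", "p", "p", "x"), b = c("a", "b", "c", "a")))
  new_net <- coexpression_network(
    data.frame(a = c("p", "p", "p", "x", "ch", "ch"),
               b = c("a", "b", "c", "a", "a", "x")))
  ann <- data.frame(gene = "ch", mechanism = "duplication", parent = "p")
  ev <- extract_events(old_net, new_net, ann)
  d <- ev$duplications
  expect_equal(d$parent_degree, 3)
  expect_equal(d$retained_count, 1)
  expect_equal(d$retained, "a")
  expect_equal(sort(strsplit(d$deleted, ";")[[1]]), c("b", "c"))
  expect_equal(d$rewired, "x")
  expect_equal(d$alpha, 1 / 3)
  expect_false(d$parent_inferred)
})

test_that("a child keeping the full parental neighbourhood has alpha 1", {
  old_net <- star_graph(4, center = "p")
  leaves <- paste0("leaf", 1:4)
  new_net <- coexpression_network(
    rbind(data.frame(a = "p", b = leaves), data.frame(a = "ch", b = leaves)))
  ev <- extract_events(old_net, new_net,
                       data.frame(gene = "ch", mechanism = "duplication",
                                  parent = "p"))
  expect_equal(ev$duplications$alpha, 1)
  expect_equal(ev$duplications$n_rewired, 0)
})

test_that("unknown parents are inferred by maximal Jaccard overlap", {
  old_net <- coexpression_network(
    data.frame(a = c("p", "p", "p", "q", "q"),
               b = c("a", "b", "c", "c", "d")))
  new_net <- coexpression_network(
    data.frame(a = c("p", "p", "p", "q", "q", "ch", "ch"),
               b = c("a", "b", "c", "c", "d", "a", "b")))
  ev <- extract_events(old_net, new_net,
                       data.frame(gene = "ch", mechanism = "duplication"))
  expect_equal(ev$duplications$parent, "p")
  expect_true(ev$duplications$parent_inferred)
})

test_that("de novo degrees and zeta come from links into the old network", {
  old_net <- path_graph(c("a", "b", "c"))  # mean degree 4/3
  new_net <- coexpression_network(
    data.frame(a = c("a", "b", "nv", "nv"), b = c("b", "c", "a", "c")))
  ev <- extract_events(old_net, new_net,
                       data.frame(gene = "nv", mechanism = "de_novo"))
  expect_equal(ev$de_novo$degree, 2)
  expect_equal(ev$de_novo$zeta, 2 / (4 / 3))
})

test_that("estimators are invariant to gene relabelling", {
  set.seed(31)
  sim <- make_annotated_series(make_seed_graph(120, m = 4, seed = 8),
                               schedule = rep(list(c(8, 2)), 2), seed = 9)
  est1 <- estimate_evolution_params(sim$series, sim$annotations)
  relabel <- function(net) {
    g <- igraph::set_vertex_attr(net, "name",
                                 value = paste0("X", igraph::V(net)$name))
    class(g) <- class(net); g
  }
  ann2 <- sim$annotations
  ann2$gene <- paste0("X", ann2$gene)
  ann2$parent <- ifelse(is.na(ann2$parent), NA, paste0("X", ann2$parent))
  est2 <- estimate_evolution_params(lapply(sim$series, relabel), ann2)
  expect_equal(est2$alpha, est1$alpha)
  expect_equal(est2$beta, est1$beta)
  expect_equal(est2$gamma, est1$gamma)
})

test_that("forward-simulated parameters are recovered from the series", {
  truth <- evolution_params(alpha = 0.13, beta = 0.80, gamma = 1.0)
  sim <- make_annotated_series(make_seed_graph(300, m = 10, seed = 5),
                               schedule = rep(list(c(30, 4)), 3),
                               truth = truth, seed = 6)
  est <- estimate_evolution_params(sim$series, sim$annotations)
  # exact event inversion: recovered rates must match the event log itself
  ev <- sim$events
  dup <- ev[ev$type == "duplication", ]
  expect_equal(mean(tapply(dup$n_retained / dup$parent_degree, dup$step, mean)),
               est$alpha, tolerance = 1e-10)
  expect_lt(abs(est$alpha - 0.13), 0.05)
  expect_lt(abs(est$beta - 0.80), 0.10)
  expect_lt(abs(est$gamma - 1.00), 0.10)
  expect_equal(est$delta, 1 - est$alpha)
})

test_that("uniformly drawn parents look random in the diagnostics", {
  set.seed(77)
  net <- make_seed_graph(500, m = c(1, 6), seed = 12)
  parents <- sample(igraph::V(net)$name, 400, replace = TRUE)
  rep_ <- randomness_diagnostics(data.frame(parent = parents), net)
  # under uniform sampling the above-median fraction of parents matches the
  # population fraction above the median (ties on integer metrics push both
  # below 1/2 together) within binomial 3 sigma
  deg <- igraph::degree(net)
  ks <- kshell_decomposition(net)
  for (i in 1:2) {
    v <- if (rep_$metric[i] == "degree") deg else ks
    p0 <- mean(v > median(v))
    sigma3 <- 3 * sqrt(p0 * (1 - p0) / 400)
    expect_lt(abs(rep_$frac_above_median[i] - p0), sigma3)
  }
  expect_lt(abs(rep_$parent_mean[1] - mean(deg)),
            3 * sd(deg) / sqrt(400))
  expect_equal(rep_$metric, c("degree", "coreness"))
})

test_that("a core hub parent sits wholly above both medians", {
  # K4 core with five pendant leaves on k1: k1 tops degree and coreness
  net <- coexpression_network(rbind(
    t(utils::combn(paste0("k", 1:4), 2)),
    cbind("k1", paste0("leaf", 1:5))))
  rep_ <- randomness_diagnostics(data.frame(parent = "k1"), net)
  expect_equal(rep_$frac_above_median, c(1, 1))
})

test_that("betweenness retention report separates cheap and costly edges", {
  # parent p: edges to a (betweenness small) and c (large); child keeps a
  old_net <- coexpression_network(
    data.frame(a = c("p", "p", "a", "c", "c2"),
               b = c("a", "c", "b", "c2", "c3")))
  new_net <- coexpression_network(
    data.frame(a = c("p", "p", "a", "c", "c2", "ch"),
               b = c("a", "c", "b", "c2", "c3", "a")))
  ev <- extract_events(old_net, new_net,
                       data.frame(gene = "ch", mechanism = "duplication",
                                  parent = "p"))
  rep_ <- betweenness_retention_report(ev)
  expect_lt(rep_$retained_mean, rep_$deleted_mean)
  expect_lt(rep_$ratio, 1)
})

test_that("equal-betweenness edges give equal retained and deleted means", {
  old_net <- cycle_graph(6)  # all edges symmetric, equal betweenness
  # child duplicates c1 keeping c2, losing c6
  new_net <- coexpression_network(
    rbind(igraph::as_edgelist(old_net, names = TRUE),
          cbind("ch", "c2")))
  ev <- extract_events(old_net, new_net,
                       data.frame(gene = "ch", mechanism = "duplication",
                                  parent = "c1"))
  rep_ <- betweenness_retention_report(ev)
  expect_equal(rep_$retained_mean, rep_$deleted_mean)
})
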