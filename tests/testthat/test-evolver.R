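test_that("parent selection is uniform over the ancestral genes", {
  snap <- network_snapshot(make_seed_graph(10, m = 2, seed = 1),
                           edge_betweenness = FALSE)
  set.seed(101)
  draws <- replicate(2e4, select_parent(snap))
  freq <- table(factor(draws, levels = snap$genes)) / 2e4
  sigma3 <- 3 * sqrt(0.1 * 0.9 / 2e4)
  expect_true(all(abs(freq - 0.1) < sigma3))
  one <- network_snapshot(coexpression_network(nodes = "only"),
                          edge_betweenness = FALSE)
  expect_equal(select_parent(one), "only")
  expect_error(select_parent(coexpression_network()), "empty")
})

test_that("edge retention keeps exactly round(alpha d_p) edges, extremes exact", {
  partners <- paste0("n", 1:6)
  b <- c(5, 1, 3, 2, 8, 4)
  set.seed(1)
  expect_equal(sort(retain_edges(partners, b, 1)), sort(partners))
  expect_equal(retain_edges(partners, b, 0), character(0))
  kept <- retain_edges(partners, b, 0.5)
  expect_length(kept, 3)  # round(0.5 * 6)
  expect_error(retain_edges(partners, c(b[-1], -1), 0.5), "negative")
  expect_error(retain_edges(character(0), numeric(0), 0.5), "no edges")
})

test_that("retention follows the weighted without-replacement law", {
  # three parental edges with betweenness (1, 1, 8): weights (0.9, 0.9, 0.2)
  # drawing one edge, so P(edge 3 kept) = 0.2/2 = 0.1
  set.seed(202)
  n <- 2e4
  kept3 <- replicate(n, retain_edges(c("e1", "e2", "e3"), c(1, 1, 8), 1 / 3) == "e3")
  sigma3 <- 3 * sqrt(0.1 * 0.9 / n)
  expect_lt(abs(mean(kept3) - 0.1), sigma3)
})

test_that("rewiring weights are proportional to coreness times degree", {
  # hub-and-spoke plus a triangle: unequal ks * d products
  net <- coexpression_network(
    data.frame(a = c("t1", "t2", "t3", "t1", "h", "h", "h"),
               b = c("t2", "t3", "t1", "h", "l1", "l2", "l3")))
  snap <- network_snapshot(net, edge_betweenness = FALSE)
  # exclude parent l1 (neighbour h): candidates t1, t2, t3, l2, l3
  w <- snap$coreness[c("t1", "t2", "t3", "l2", "l3")] *
    snap$degree[c("t1", "t2", "t3", "l2", "l3")]
  p_t1 <- w["t1"] / sum(w)
  set.seed(303)
  n <- 2e4
  hits <- replicate(n, "t1" %in% rewire_targets(snap, "l1", beta = NULL, m = 1))
  sigma3 <- 3 * sqrt(p_t1 * (1 - p_t1) / n)
  expect_lt(abs(mean(hits) - p_t1), sigma3)
})

test_that("two-candidate weight arithmetic is exact for de novo attachment", {
  # star S3 plus an isolated triangle member set giving ks*d of 9 vs 1 is
  # hard to plant exactly; check the sampling law directly on frozen weights
  net <- coexpression_network(data.frame(a = c("a", "a", "a", "b"),
                                         b = c("b", "c", "d", "c")))
  snap <- network_snapshot(net, edge_betweenness = FALSE)
  w <- snap$coreness * snap$degree
  p_a <- unname(w["a"] / sum(w))
  set.seed(404)
  n <- 2e4
  hits <- replicate(n, "a" %in% attach_de_novo(snap, gamma = NULL, m = 1))
  expect_lt(abs(mean(hits) - p_a), 3 * sqrt(p_a * (1 - p_a) / n))
})

test_that("zero-weight candidates are never drawn and shortfall errors", {
  net <- coexpression_network(data.frame(a = "a", b = "b"),
                              nodes = c("a", "b", "iso"))
  snap <- network_snapshot(net, edge_betweenness = FALSE)
  set.seed(1)
  for (i in 1:50) {
    expect_false("iso" %in% attach_de_novo(snap, gamma = NULL, m = 2))
  }
  expect_error(attach_de_novo(snap, gamma = NULL, m = 3), "positive-weight")
  expect_equal(sort(attach_de_novo(snap, gamma = NULL, m = 3,
                                   allow_shortfall = TRUE)), c("a", "b"))
})

test_that("a zero-addition step is the identity on the network", {
  net <- make_seed_graph(30, m = 2, seed = 3)
  res <- evolve_step_model1(net, 0, 0, evolution_params(), seed = 1)
  expect_equal(igraph::vcount(res$network), igraph::vcount(net))
  expect_equal(edge_set(res$network), edge_set(net))
  expect_equal(nrow(res$events), 0)
})

test_that("each child degree obeys the frozen count rules", {
  params <- evolution_params(alpha = 0.3, beta = 0.5, gamma = 1.2)
  net <- make_seed_graph(200, m = 4, seed = 10)
  res <- evolve_step_model1(net, 25, 5, params, seed = 11)
  snap <- res$snapshot
  ev <- res$events
  dup <- ev[ev$type == "duplication", ]
  m_re <- floor(snap$mean_degree * params$beta + 0.5)
  expect_equal(dup$n_retained,
               pmin(pmax(floor(params$alpha * dup$parent_degree + 0.5), 0),
                    dup$parent_degree))
  expect_true(all(dup$n_rewired == m_re))
  novo <- ev[ev$type == "de_novo", ]
  expect_true(all(novo$n_rewired == floor(snap$mean_degree * params$gamma + 0.5)))
  # node conservation and no new-new edges
  expect_equal(igraph::vcount(res$network), 230)
  new_names <- ev$child
  el <- igraph::as_edgelist(res$network, names = TRUE)
  new_new <- el[, 1] %in% new_names & el[, 2] %in% new_names
  expect_false(any(new_new))
  expect_equal(igraph::count_multiple(res$network),
               rep(1, igraph::ecount(res$network)))
})

test_that("rewired partners never duplicate inherited edges or the parent", {
  params <- evolution_params(alpha = 0.5, beta = 1.0, gamma = 1.0)
  net <- make_seed_graph(100, m = 3, seed = 20)
  res <- evolve_step_model1(net, 20, 0, params, seed = 21)
  snap <- res$snapshot
  for (r in seq_len(nrow(res$events))) {
    ev <- res$events[r, ]
    rew <- strsplit(ev$rewired, ";")[[1]]
    pn <- snap$neighbours[[ev$parent]]
    expect_length(intersect(rew, c(pn, ev$parent)), 0)
  }
})

test_that("model 2 derives counts from duration by round-half-up", {
  params <- evolution_params()  # rates 3.58 and 0.31
  net <- make_seed_graph(60, m = 2, seed = 2)
  res <- evolve_step_model2(net, t = 65.05, params, seed = 1)
  expect_equal(res$n_dup, 233)   # 3.58 * 65.05 = 232.88
  expect_equal(res$n_novo, 20)   # 0.31 * 65.05 = 20.17
  res1 <- evolve_step_model2(net, t = 1, params, seed = 1)
  expect_equal(res1$n_dup, 4)    # round-half-up of 3.58
  expect_equal(res1$n_novo, 0)   # round-half-up of 0.31
  zero <- evolution_params(r_dup = 0, r_novo = 0)
  res0 <- evolve_step_model2(net, t = 10, zero, seed = 1)
  expect_equal(edge_set(res0$network), edge_set(net))
  expect_error(evolve_step_model2(net, t = -1, params, seed = 1), "positive")
})

test_that("the full six-step interval schedule gives deterministic counts", {
  iv <- repartition_branches()$timeline$interval[-1]
  n1 <- floor(3.58 * iv + 0.5)
  n2 <- floor(0.31 * iv + 0.5)
  expect_equal(n1, c(233, 252, 266, 220, 236, 174))
  expect_equal(n2, c(20, 22, 23, 19, 20, 15))
})

test_that("traditional model deletes inherited edges as independent Bernoulli", {
  net <- make_seed_graph(150, m = 5, seed = 30)
  keep_all <- evolve_traditional(net, 10, evolution_params(delta = 0), seed = 3)
  ev <- keep_all$events
  expect_equal(ev$n_retained, ev$parent_degree)
  drop_all <- evolve_traditional(net, 10, evolution_params(delta = 1), seed = 3)
  expect_true(all(drop_all$events$n_retained == 0))

  # delta = 0.8711: retained counts binomial with mean (1 - delta) d_p
  params <- evolution_params(alpha = 0.1289)
  res <- evolve_traditional(net, 400, params, seed = 4)
  dup <- res$events
  z <- (sum(dup$n_retained) - 0.1289 * sum(dup$parent_degree)) /
    sqrt(sum(dup$parent_degree * 0.1289 * 0.8711))
  expect_lt(abs(z), 3)
})

test_that("multi-step runs chain snapshots and re-freeze between steps", {
  net <- make_seed_graph(80, m = 3, seed = 40)
  run <- run_evolution(net, rep(list(c(5, 1)), 3), evolution_params(),
                       model = "model1", seed = 7, topology = FALSE)
  sizes <- vapply(run$series, igraph::vcount, numeric(1))
  expect_equal(sizes, c(80, 86, 92, 98))
  expect_equal(sort(unique(run$events$step)), 1:3)
  # step-2 children may attach to step-1 children (they are then ancestral)
  expect_true(all(run$events$child %in% igraph::V(run$series[[4]])$name))
})

test_that("identical seeds give bit-identical event logs", {
  net <- make_seed_graph(80, m = 3, seed = 40)
  r1 <- run_evolution(net, rep(list(c(6, 2)), 2), evolution_params(),
                      seed = 99, topology = FALSE)
  r2 <- run_evolution(net, rep(list(c(6, 2)), 2), evolution_params(),
                      seed = 99, topology = FALSE)
  expect_identical(r1$events, r2$events)
  expect_equal(edge_set(r1$series[[3]]), edge_set(r2$series[[3]]))
  r3 <- run_evolution(net, rep(list(c(6, 2)), 2), evolution_params(),
                      seed = 100, topology = FALSE)
  expect_false(identical(r1$events, r3$events))
})

test_that("partner draws prefer high degree and coreness (rich-gets-richer)", {
  set.seed(55)
  net <- make_seed_graph(300, m = c(1, 6), seed = 50)
  snap <- network_snapshot(net, edge_betweenness = FALSE)
  partners <- character(0)
  for (i in 1:200) partners <- c(partners, attach_de_novo(snap, gamma = 1))
  expect_gt(mean(snap$degree[partners]), mean(snap$degree))
  expect_gt(mean(snap$coreness[partners]), mean(snap$coreness))
})

test_that("retained parental edges have lower betweenness than deleted ones", {
  set.seed(66)
  net <- make_seed_graph(200, m = 4, seed = 60)
  snap <- network_snapshot(net)
  kept_b <- numeric(0); lost_b <- numeric(0)
  for (i in 1:500) {
    parent <- select_parent(snap)
    pn <- snap$neighbours[[parent]]
    if (length(pn) < 2) next
    b <- unname(snap$edge_betweenness[coevonet:::edge_key(parent, pn)])
    kept <- retain_edges(pn, b, alpha = 0.5)
    kept_b <- c(kept_b, b[pn %in% kept])
    lost_b <- c(lost_b, b[!pn %in% kept])
  }
  expect_gt(length(kept_b), 100)
  expect_lt(mean(kept_b), mean(lost_b))
})
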