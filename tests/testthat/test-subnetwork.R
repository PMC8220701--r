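test_that("single chain and diamond give the expected paths", {
  net <- as_gene_network(tibble::tibble(
    source = c("s", "a", "s", "b"),
    target = c("a", "t", "b", "t"),
    type = "regulatory"))
  w <- c("a\rt" = 0.8, "b\rt" = 0.4, "s\ra" = 0.9, "s\rb" = 0.5)
  net$weight <- unname(w[paste(net$source, net$target, sep = "\r")])
  kb <- k_best_paths(net, "s", "t", k = 5, penalty_c = 1)
  expect_equal(nrow(kb), 2L)
  # both 2-edge paths, ordered by cost: via a (0.1+0.2) < via b (0.5+0.6)
  expect_equal(kb$cost, c(0.3 + 2e-3, 1.1 + 2e-3), tolerance = 1e-9)
  expect_equal(kb$nodes[[1]], c("s", "a", "t"))
  expect_equal(kb$nodes[[2]], c("s", "b", "t"))

  # chain with no alternative: exactly one path, cost = sum of edge costs
  chain <- as_gene_network(tibble::tibble(
    source = c("s", "a"), target = c("a", "t"), type = "regulatory"))
  chain$weight <- c(0.5, 0.5)
  kb2 <- k_best_paths(chain, "s", "t", k = 5, penalty_c = 2)
  expect_equal(nrow(kb2), 1L)
  expect_equal(kb2$cost, 2 * (2 * 0.5) + 2e-3, tolerance = 1e-12)

  expect_message(kb3 <- k_best_paths(chain, "zz", "t"), "skipped")
  expect_equal(nrow(kb3), 0L)
})

test_that("k-best bounded paths equal brute force on 200 random graphs", {
  set.seed(100)
  graph_seeds <- sample.int(1e6, 200)
  for (gs in graph_seeds) {
    net <- random_small_network(n_nodes = sample(4:7, 1),
                                n_edges = sample(6:14, 1), seed = gs)
    if (nrow(net) == 0) next
    nodes <- network_nodes(net)
    seed <- sample(nodes, 1)
    targets <- sample(setdiff(nodes, seed),
                      min(3, length(nodes) - 1))
    penalty <- round(runif(1, 0.1, 5), 3)
    k <- sample(1:4, 1)
    kb <- k_best_paths(net, seed, targets, k = k, max_len = 4,
                       penalty_c = penalty)
    oracle <- oracle_k_best(
      oracle_enumerate_paths(net, seed, targets, 4, penalty), k)
    expect_equal(nrow(kb), nrow(oracle), info = paste("graph", gs))
    if (nrow(kb) == 0) next
    got <- kb[order(kb$target, kb$cost, kb$n_edges,
                    vapply(kb$nodes, paste, "", collapse = "|")), ]
    want <- oracle[order(oracle$target, oracle$cost, oracle$n_edges,
                         oracle$key), ]
    expect_equal(got$target, want$target, info = paste("graph", gs))
    expect_equal(got$cost, want$cost, tolerance = 1e-9,
                 info = paste("graph", gs))
    expect_equal(vapply(got$nodes, paste, "", collapse = "|"), want$key,
                 info = paste("graph", gs))
  }
})

test_that("greedy selection solves the toy cases exactly", {
  # two seeds joined by one 2-edge path
  ec <- c(x = 0.3, y = 0.4)
  p <- tibble::tibble(source = "a", target = "b", cost = 0.7,
                      edges = list(c("x", "y")))
  sel <- select_subnetwork(p, c("a", "b"), ec)
  expect_equal(sel$connected_seeds, c("a", "b"))
  expect_equal(sel$n_edges, 2L)
  expect_equal(sel$selection_score, 2 - 0.7)

  # cheap 2-edge path beats expensive 4-edge alternative
  ec2 <- c(c1 = 0.1, c2 = 0.1, e1 = 1, e2 = 1, e3 = 1, e4 = 1)
  p2 <- tibble::tibble(
    source = c("a", "a"), target = c("b", "b"),
    cost = c(0.2, 4),
    edges = list(c("c1", "c2"), c("e1", "e2", "e3", "e4")))
  sel2 <- select_subnetwork(p2, c("a", "b"), ec2)
  expect_equal(sort(sel2$edges), c("c1", "c2"))

  # empty candidate set is a valid empty subnetwork
  sel3 <- select_subnetwork(p2[0, ], c("a", "b"), ec2)
  expect_equal(sel3$n_edges, 0L)
  expect_equal(sel3$selection_score, 0)
})

test_that("greedy parsimony is near the exhaustive optimum on small instances", {
  # the greedy always connects every connectable seed; parsimony is
  # measured as its total edge cost against the cheapest path subset
  # (exhaustive over all subsets) achieving at least the same coverage
  set.seed(200)
  ratios <- c()
  for (rep in 1:25) {
    n_seeds <- sample(3:5, 1)
    seeds <- paste0("s", seq_len(n_seeds))
    n_paths <- sample(5:12, 1)
    n_keys <- sample(6:10, 1)
    keys <- paste0("e", seq_len(n_keys))
    ec <- stats::setNames(round(runif(n_keys, 0.05, 1.2), 3), keys)
    paths <- tibble::tibble(
      source = sample(seeds, n_paths, replace = TRUE),
      target = sample(seeds, n_paths, replace = TRUE),
      edges = lapply(seq_len(n_paths), function(i)
        sample(keys, sample(1:4, 1))))
    paths <- paths[paths$source != paths$target, ]
    if (nrow(paths) == 0) next
    paths$cost <- vapply(paths$edges, function(e) sum(ec[e]), numeric(1))
    paths <- paths[order(paths$cost), ]
    sel <- select_subnetwork(paths, seeds, ec)
    greedy_cost <- sum(ec[sel$edges])
    best_cost <- Inf
    for (mask in seq_len(2^nrow(paths)) - 1L) {
      idx <- which(bitwAnd(mask, 2^(seq_len(nrow(paths)) - 1)) > 0)
      if (length(idx) == 0) next
      conn <- unique(c(paths$source[idx], paths$target[idx]))
      if (!all(sel$connected_seeds %in% conn)) next
      best_cost <- min(best_cost,
                       sum(ec[unique(unlist(paths$edges[idx]))]))
    }
    ratios <- c(ratios, greedy_cost / best_cost)
  }
  expect_lte(max(ratios), 2)
  expect_lte(mean(ratios), 1.2)
})

test_that("Jaccard definitions behave at the boundary cases", {
  expect_equal(suppnet:::jaccard(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(suppnet:::jaccard(character(0), character(0)), 1)
  expect_equal(suppnet:::jaccard(c("a"), c("b")), 0)
  expect_equal(suppnet:::mean_pairwise_jaccard(
    list(c("a", "b"), c("a", "b"), c("a", "b"))), 1)
  expect_equal(suppnet:::mean_pairwise_jaccard(
    list("a", "b", "c")), 0)
})

test_that("a deterministic selection yields stability 1", {
  # two seeds, one path: every resample keeps both seeds (ceiling(0.8*2)
  # = 2) and selects the same two edges
  net <- as_gene_network(tibble::tibble(
    source = c("a", "mid"), target = c("mid", "b"), type = "ppi"))
  net$weight <- 0.9
  stab <- subnetwork_stability(net, c("a", "b"), penalty_c = 1,
                               resamples = 5, rng_seed = 3)
  expect_equal(stab, 1)

  # full-fraction resampling of a star module is identical by definition
  star <- as_gene_network(tibble::tibble(
    source = "hub", target = paste0("m", 1:5), type = "ppi"))
  star$weight <- 0.95
  stab2 <- subnetwork_stability(star, c("hub", paste0("m", 1:5)),
                                penalty_c = 1, resamples = 5,
                                fraction = 1, rng_seed = 3)
  expect_equal(stab2, 1)
})

test_that("disconnected seeds give an empty result with a warning", {
  # two seeds at distance 6: no path within 4 edges
  chain <- as_gene_network(tibble::tibble(
    source = paste0("n", 1:6), target = paste0("n", 2:7),
    type = "regulatory"))
  chain$weight <- 0.9
  cfg <- pipeline_config(resamples = 3)
  expect_warning(
    sub <- infer_subnetworks(chain, c("n1", "n7"), cfg),
    "no penalty")
  expect_equal(nrow(sub$edges), 0L)
  expect_equal(glance(sub)$n_components, 0L)
})

test_that("subnetwork size never grows as the penalty rises", {
  cfg <- pipeline_config(resamples = 3)
  sim <- simulate_study(cfg, n_genes = 400, rng_seed = 6,
                        module_size = c(4, 6),
                        labels_spec = list(
                          counts = c(A = 14, B = 8, C = 14, D = 4, E = 4,
                                     F = 4),
                          cores = c(A = 6, B = 2, C = 6)))
  de <- de_test(sim$expr, cfg$reference_line)
  sc <- score_network(de, sim$network)
  sub <- infer_subnetworks(sc$network, sim$truth$module_seeds, cfg,
                           scores = sc$scores)
  expect_true(all(diff(sub$sweep$n_edges) <= 0))
  expect_true(all(diff(sub$sweep$penalty) > 0))
})

test_that("connector genes sit on paths, never as leaves", {
  cfg <- pipeline_config(resamples = 3)
  sim <- simulate_study(cfg, n_genes = 600, rng_seed = 12,
                        module_size = c(6, 8),
                        labels_spec = list(
                          counts = c(A = 20, B = 10, C = 20, D = 4,
                                     E = 4, F = 4),
                          cores = c(A = 8, B = 3, C = 8)))
  de <- de_test(sim$expr, cfg$reference_line)
  sc <- score_network(de, sim$network)
  sub <- infer_subnetworks(sc$network, sim$truth$module_seeds, cfg,
                           scores = sc$scores)
  conns <- sub$nodes$gene[sub$nodes$connector]
  if (length(conns) > 0) {
    deg <- table(c(sub$edges$source, sub$edges$target))
    expect_true(all(deg[conns] >= 2))
  }
  expect_gt(nrow(sub$nodes), 0)
})

test_that("recovery metrics have their closed-form boundary values", {
  mk_set <- function(nodes, comp, edges) {
    structure(list(
      nodes = tibble::tibble(gene = nodes, component = comp,
                             is_seed = TRUE, connector = FALSE,
                             score = 1),
      edges = edges, components = tibble::tibble(),
      sweep = tibble::tibble(), seeds = nodes),
      class = "subnetwork_set")
  }
  mod_edges <- as_gene_network(tibble::tibble(
    source = c("a", "b"), target = c("b", "c"), type = "ppi"))
  truth <- structure(list(planted_modules = list(
    list(genes = c("a", "b", "c"), seeds = c("a", "b", "c"),
         connectors = character(0), edges = mod_edges))),
    class = "synthetic_truth")

  full <- mk_set(c("a", "b", "c"), c(1L, 1L, 1L),
                 dplyr::mutate(mod_edges, weight = 1, component = 1L))
  r1 <- recover_planted(full, truth)
  expect_equal(c(r1$node_precision, r1$node_recall, r1$node_f1),
               c(1, 1, 1))
  expect_equal(r1$edge_f1, 1)

  empty <- mk_set(character(0), integer(0),
                  tibble::tibble(source = character(),
                                 target = character(),
                                 type = character(), weight = numeric(),
                                 component = integer()))
  r2 <- recover_planted(empty, truth)
  expect_equal(r2$node_recall, 0)

  half <- mk_set(c("a", "b"), c(1L, 1L),
                 dplyr::mutate(mod_edges[1, ], weight = 1,
                               component = 1L))
  r3 <- recover_planted(half, truth)
  expect_equal(r3$node_precision, 1)
  expect_equal(r3$node_recall, 2 / 3)
})
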