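test_that("a zero-label specification yields pure noise", {
  sim <- simulate_expression(
    n_genes = 100, rng_seed = 2,
    labels_spec = list(counts = c(A = 0, B = 0, C = 0, D = 0, E = 0,
                                  F = 0),
                       cores = c(A = 0, B = 0, C = 0)))
  expect_true(all(sim$truth$group_of$label == "none"))
  expect_equal(nrow(sim$truth$effect_of), 0L)
  # centered per gene, values are just baseline + noise: line means agree
  m <- sim$expr$values
  lines <- sim$expr$samples$line
  mut <- rowMeans(m[, lines == "bri1-5"])
  ref <- rowMeans(m[, lines == "WS2"])
  expect_lt(max(abs(mut - ref)), 1.5)
})

test_that("simulation is bit-identical under the same seed", {
  spec <- list(counts = c(A = 10, B = 6, C = 10, D = 4, E = 4, F = 4),
               cores = c(A = 4, B = 2, C = 4))
  a <- simulate_expression(n_genes = 200, rng_seed = 5,
                           labels_spec = spec)
  b <- simulate_expression(n_genes = 200, rng_seed = 5,
                           labels_spec = spec)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$truth$effect_of, b$truth$effect_of)
  na <- simulate_network(a$truth, n_modules = 2, module_size = c(4, 5),
                         rng_seed = 5)
  nb <- simulate_network(b$truth, n_modules = 2, module_size = c(4, 5),
                         rng_seed = 5)
  expect_identical(na$network, nb$network)
})

test_that("undetectable planted effects are rejected", {
  expect_error(
    simulate_expression(n_genes = 100, effect_range = c(0.3, 1)),
    "log2")
})

test_that("planted labels are recovered exactly with strong effects", {
  # large effects, tiny noise: thresholding has ideal power and the
  # DE + classification pipeline must reproduce the planted labels
  sim <- simulate_expression(
    n_genes = 400, rng_seed = 3,
    effect_range = c(2.5, 4),
    noise = list(d0 = 50, s0_sq = 0.0025),
    labels_spec = list(counts = c(A = 20, B = 15, C = 20, D = 10, E = 10,
                                  F = 10),
                       cores = c(A = 8, B = 5, C = 8)))
  cfg <- pipeline_config()
  de <- de_test(sim$expr, cfg$reference_line)
  groups <- classify_groups(de, cfg$mutant_line, cfg$suppressor_lines)
  truth <- sim$truth$group_of
  merged <- dplyr::inner_join(groups, truth, by = "gene",
                              suffix = c("_got", "_true"))
  expect_equal(as.character(merged$label_got),
               as.character(merged$label_true))
  expect_equal(merged$core_got, merged$core_true)
})

test_that("background max-logFC matches the reported null parameters", {
  sim <- simulate_expression(n_genes = 5000, rng_seed = 4)
  de <- de_test(sim$expr, "WS2")
  sel <- select_max_logfc(de)
  bg <- sim$truth$group_of$gene[sim$truth$group_of$label == "none"]
  nm <- fit_null(sel$x[sel$gene %in% bg])
  expect_equal(nm$mu, unname(sim$truth$null_params["mu"]),
               tolerance = 0.02)
  expect_equal(nm$sigma, unname(sim$truth$null_params["sigma"]),
               tolerance = 0.05)
})

test_that("background graph size follows the attachment model", {
  sim <- simulate_expression(
    n_genes = 300, rng_seed = 6,
    labels_spec = list(counts = c(A = 0, B = 0, C = 0, D = 0, E = 0,
                                  F = 0),
                       cores = c(A = 0, B = 0, C = 0)))
  # zero planted modules: a pure background graph
  net <- simulate_network(sim$truth, n_modules = 0, rng_seed = 6)
  m <- 4  # background_degree 8 / 2
  expected <- m * (300 - m) + choose(m, 2)
  expect_lt(abs(nrow(net$network) - expected), 0.05 * expected)
  expect_equal(length(net$truth$planted_modules), 0L)
  # type mixture roughly follows the stated proportions
  props <- table(net$network$type) / nrow(net$network)
  expect_equal(unname(props["ppi"]), 0.4965, tolerance = 0.1)
})

test_that("module construction respects its connectivity contract", {
  sim <- simulate_expression(n_genes = 500, rng_seed = 7,
                             labels_spec = list(
                               counts = c(A = 16, B = 10, C = 16, D = 4,
                                          E = 4, F = 4),
                               cores = c(A = 6, B = 3, C = 6)))
  net <- simulate_network(sim$truth, n_modules = 3,
                          module_size = c(3, 6), rng_seed = 7)
  for (mod in net$truth$planted_modules) {
    g <- igraph::graph_from_data_frame(
      mod$edges[, c("source", "target")], directed = FALSE)
    expect_true(igraph::is_connected(g))
    expect_lte(igraph::diameter(g), 4)
    expect_true(length(mod$connectors) %in% 1:2)
    # connectors are non-DE genes
    labels <- sim$truth$group_of$label[
      match(mod$connectors, sim$truth$group_of$gene)]
    expect_true(all(labels == "none"))
    # seeds are planted DE genes from groups A-C
    slabels <- sim$truth$group_of$label[
      match(mod$seeds, sim$truth$group_of$gene)]
    expect_true(all(slabels %in% c("A", "B", "C")))
  }
  expect_error(simulate_network(sim$truth, path_length = 2), "path_length")
})
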