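test_that("quantile normalization maps samples onto the mean distribution", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  rownames(m) <- paste0("g", 1:3)
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))

  # identical samples are a fixed point
  m2 <- cbind(a = c(5, 1, 3), b = c(5, 1, 3))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(quantile_normalize(m2), m2)

  # defining property: identical sorted value vectors afterwards
  set.seed(1)
  m3 <- matrix(rnorm(200), 50, 4,
               dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  qn3 <- quantile_normalize(m3)
  ref <- unname(sort(qn3[, 1]))
  for (j in 2:4) expect_equal(unname(sort(qn3[, j])), ref)

  # ties receive the mean of the quantile values they span
  m4 <- cbind(a = c(1, 1, 5), b = c(2, 4, 6))
  rownames(m4) <- paste0("g", 1:3)
  qn4 <- quantile_normalize(m4)
  ref4 <- rowMeans(apply(m4, 2, sort))
  expect_equal(unname(qn4[1:2, "a"]), rep(mean(ref4[1:2]), 2))

  expect_error(quantile_normalize(cbind(a = c(1, NA), b = c(1, 2))),
               "issing")
})

test_that("tie-free quantile normalization agrees with limma", {
  skip_if_not_installed("limma")
  set.seed(2)
  m <- matrix(rnorm(300), 60, 5,
              dimnames = list(paste0("g", 1:60), paste0("s", 1:5)))
  expect_equal(unname(quantile_normalize(m)),
               unname(limma::normalizeQuantiles(m)), tolerance = 1e-12)
})

test_that("probe collapsing drops non-unique probes and averages", {
  m <- rbind(p1 = c(2, 2), p2 = c(4, 4), p3 = c(9, 9), p4 = c(7, 7))
  colnames(m) <- c("S1", "S2")
  meta <- tibble::tibble(sample = c("S1", "S2"), line = c("L1", "L1"),
                         replicate = 1:2)
  es <- expression_set(m, meta)
  map <- tibble::tibble(probe = c("p1", "p2", "p3", "p3", "p4"),
                        gene = c("gA", "gA", "gB", "gC", "gD"))
  out <- collapse_probes(es, map)
  # p3 maps to two genes -> removed entirely; gB and gC absent
  expect_equal(rownames(out$values), c("gA", "gD"))
  expect_equal(unname(out$values["gA", ]), c(3, 3))
  # one probe per gene is the identity
  expect_equal(unname(out$values["gD", ]), c(7, 7))
})

test_that("moderated DE has the stated limits and invariances", {
  eff <- matrix(c(0, 1.2), 2, 1,
                dimnames = list(c("g_null", "g_de"), "bri1-5"))
  eff <- rbind(eff, matrix(0, 18, 1,
                           dimnames = list(paste0("bg", 1:18), "bri1-5")))
  es <- tiny_expression(eff, noise_sd = 0.2, seed = 11)
  de <- moderated_de(es, "bri1-5", "WS2")

  # identical group means: logFC ~ 0; large planted shift recovered
  expect_lt(abs(de$logFC[de$gene == "g_null"]), 0.5)
  expect_equal(unname(de$logFC[de$gene == "g_de"]), 1.2, tolerance = 0.4)

  # d0 = 0 recovers the ordinary pooled two-sample t
  de0 <- moderated_de(es, "bri1-5", "WS2", d0_override = 0)
  i1 <- es$samples$line == "bri1-5"
  i0 <- es$samples$line == "WS2"
  tt <- apply(es$values, 1, function(v)
    stats::t.test(v[i1], v[i0], var.equal = TRUE)$statistic)
  expect_equal(unname(de0$t), unname(tt), tolerance = 1e-10)

  # invariance to adding a constant to all samples of a gene
  es2 <- es
  es2$values["g_de", ] <- es2$values["g_de", ] + 100
  de2 <- moderated_de(es2, "bri1-5", "WS2")
  expect_equal(de2$t, de$t, tolerance = 1e-8)

  # a line with < 2 replicates is an error
  es3 <- es
  es3$samples$line[es3$samples$line == "WS2"][2:3] <- "other"
  expect_error(moderated_de(es3, "bri1-5", "WS2"), "replicates")
})

test_that("moderated DE tracks limma on shared data", {
  skip_if_not_installed("limma")
  sim <- simulate_expression(n_genes = 600, rng_seed = 5,
                             labels_spec = list(
                               counts = c(A = 30, B = 0, C = 0, D = 0,
                                          E = 0, F = 0),
                               cores = c(A = 15, B = 0, C = 0)))
  es <- sim$expr
  keep <- es$samples$line %in% c("WS2", "bri1-5")
  sub <- expression_set(es$values[, keep], es$samples[keep, ])
  ours <- moderated_de(sub, "bri1-5", "WS2")
  design <- stats::model.matrix(~ factor(sub$samples$line,
                                         levels = c("WS2", "bri1-5")))
  fit <- limma::eBayes(limma::lmFit(sub$values, design))
  expect_equal(unname(ours$logFC), unname(fit$coefficients[, 2]),
               tolerance = 1e-10)
  expect_gt(stats::cor(ours$t, fit$t[, 2]), 0.9999)
  prior <- attr(ours, "prior")
  expect_equal(prior$d0, fit$df.prior, tolerance = 0.1 * fit$df.prior)
})

test_that("null p-values from the moderated test are uniform", {
  sim <- simulate_expression(n_genes = 5000, rng_seed = 9,
                             labels_spec = list(
                               counts = c(A = 0, B = 0, C = 0, D = 0,
                                          E = 0, F = 0),
                               cores = c(A = 0, B = 0, C = 0)))
  de <- moderated_de(sim$expr, "bri1-5", "WS2")
  ks <- stats::ks.test(de$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(3)
  for (i in 1:6) {
    p <- round(runif(6), 3)
    for (j in 1:5) {
      pp <- sample(p)
      expect_equal(bh_adjust(pp), oracle_bh(pp))
    }
  }
})

test_that("threshold flags follow |logFC| >= log2(fc) and FDR", {
  de <- tibble::tibble(
    logFC = c(0.60, 2, -0.7, 0.3),
    adj_p = c(0.01, 0.06, 0.001, 0.001))
  out <- apply_thresholds(de, 1.5, 0.05)
  expect_equal(out$de_flag, c(TRUE, FALSE, TRUE, FALSE))
  # adjusted p is never below raw p, and flags respect the invariant
  sim <- simulate_expression(n_genes = 400, rng_seed = 13)
  det <- de_test(sim$expr, "WS2")
  expect_true(all(det$adj_p >= det$p - 1e-12))
  expect_equal(det$de_flag,
               det$adj_p <= 0.05 & abs(det$logFC) >= log2(1.5))
})

test_that("the DE stage recovers planted effects with high sensitivity and controlled FDR", {
  sim <- simulate_expression(n_genes = 2000, rng_seed = 20,
                             labels_spec = list(
                               counts = c(A = 30, B = 18, C = 37, D = 33,
                                          E = 17, F = 10),
                               cores = c(A = 12, B = 3, C = 15)))
  de <- de_test(sim$expr, "WS2")
  truth_pairs <- paste(sim$truth$effect_of$gene, sim$truth$effect_of$line)
  flagged <- paste(de$gene, de$line)[de$de_flag]
  sensitivity <- mean(truth_pairs %in% flagged)
  fdr <- mean(!(flagged %in% truth_pairs))
  expect_gte(sensitivity, 0.9)
  expect_lte(fdr, 0.1)
})

test_that("PCA QC separates lines and returns orthogonal scores", {
  eff <- matrix(c(3, -3, 0, 2, 0, -2), 2, 3,
                dimnames = list(c("g1", "g2"),
                                c("bri1-5", "bri1-5/brs1-1D",
                                  "bri1-5/bak1-1D")))
  eff <- rbind(eff, matrix(0, 30, 3,
                           dimnames = list(paste0("b", 1:30),
                                           colnames(eff))))
  es <- tiny_expression(eff, noise_sd = 0.02, seed = 21)
  qc <- pca_qc(es)
  expect_lt(qc$dispersion[["within"]], qc$dispersion[["between"]])
  expect_lt(qc$dispersion[["ratio"]], 1)
  sc <- as.matrix(qc$scores[, c("PC1", "PC2")])
  expect_lt(abs(crossprod(sc[, 1], sc[, 2])), 1e-8)

  # identical samples get identical scores
  m <- es$values
  m[, 2] <- m[, 1]
  es2 <- expression_set(m, es$samples)
  qc2 <- pca_qc(es2)
  expect_equal(unlist(qc2$scores[1, c("PC1", "PC2")]),
               unlist(qc2$scores[2, c("PC1", "PC2")]), tolerance = 1e-8)
})
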