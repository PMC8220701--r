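# Independent oracles used across the suite.  Everything here is written
# directly from first principles (definitions, brute force, enumeration)
# and must stay independent of the package implementations it checks.

# --- Benjamini-Hochberg step-up, literal definition ---------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  adj[o] <- p[o] * m / seq_len(m)
  # monotonicity: running minimum from the largest rank down
  adj[o] <- rev(cummin(rev(adj[o])))
  pmin(adj, 1)
}

# --- group classification truth table ----------------------------------
# Flags: mutant, s1, s2, s3 (s1/s2/s3 = first/second/third suppressor).
oracle_group_label <- function(m, s1, s2, s3) {
  s <- c(s1, s2, s3)
  n_de <- sum(s)
  n_not <- 3 - n_de
  if (m && n_not >= 2) {
    return(list(label = "A", core = n_de == 0))
  }
  if (!m && n_de >= 2) {
    return(list(label = "B", core = n_de == 3))
  }
  if (m && n_de >= 2) {
    return(list(label = "C", core = n_de == 3))
  }
  if (!m && n_de == 1) {
    return(list(label = c("D", "E", "F")[which(s)], core = FALSE))
  }
  list(label = "none", core = FALSE)
}

# --- brute-force bounded simple path enumeration ------------------------
# All simple paths from `seed` with at most `max_len` edges, following
# directed edges source -> target and ppi edges both ways; every prefix
# ending at a target is recorded.  Returns a data frame of node-sequence
# strings with costs.
oracle_enumerate_paths <- function(edges, seed, targets, max_len,
                                   penalty, eps = 1e-3) {
  arcs <- rbind(
    data.frame(from = edges$source, to = edges$target, w = edges$weight),
    data.frame(from = edges$target[edges$type == "ppi"],
               to = edges$source[edges$type == "ppi"],
               w = edges$weight[edges$type == "ppi"]))
  out <- list()
  recurse <- function(path, cost) {
    v <- path[length(path)]
    if (length(path) > 1 && v %in% targets) {
      out[[length(out) + 1]] <<- data.frame(
        target = v, cost = cost, n_edges = length(path) - 1,
        key = paste(path, collapse = "|"))
    }
    if (length(path) - 1 >= max_len) return()
    nxt <- arcs[arcs$from == v, , drop = FALSE]
    for (i in seq_len(nrow(nxt))) {
      if (nxt$to[i] %in% path) next
      recurse(c(path, nxt$to[i]), cost + penalty * (1 - nxt$w[i]) + eps)
    }
  }
  if (seed %in% c(edges$source, edges$target)) recurse(seed, 0)
  if (length(out) == 0) {
    return(data.frame(target = character(), cost = numeric(),
                      n_edges = integer(), key = character()))
  }
  do.call(rbind, out)
}

# k-best truncation of the oracle enumeration, same ordering contract
oracle_k_best <- function(enum, k) {
  enum <- enum[order(enum$target, enum$cost, enum$n_edges, enum$key), ]
  keep <- unlist(lapply(split(seq_len(nrow(enum)), enum$target),
                        function(i) utils::head(i, k)))
  enum[sort(keep), ]
}

# --- random small network fixture ---------------------------------------
random_small_network <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nodes <- paste0("n", seq_len(n_nodes))
  src <- sample(nodes, n_edges, replace = TRUE)
  tgt <- sample(nodes, n_edges, replace = TRUE)
  type <- sample(c("regulatory", "ppi", "metabolic"), n_edges,
                 replace = TRUE)
  net <- as_gene_network(tibble::tibble(source = src, target = tgt,
                                        type = type))
  net$weight <- round(stats::runif(nrow(net)), 3)
  net
}

# --- hypergeometric upper tail by exhaustive enumeration ----------------
oracle_hyper_upper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_set <- function(cols) colSums(matrix(cols <= K, nrow = n))
  mean(in_set(draws) >= k)
}

# --- tiny expression fixture --------------------------------------------
# deterministic 5-line x n_rep expression set with given per-gene,
# per-line mean shifts
tiny_expression <- function(effects, n_rep = 3, noise_sd = 0.05,
                            seed = 42,
                            lines = c("WS2", "bri1-5", "bri1-5/brs1-1D",
                                      "bri1-5/bri1-1D",
                                      "bri1-5/bak1-1D")) {
  set.seed(seed)
  genes <- rownames(effects)
  stopifnot(all(colnames(effects) %in% lines))
  samples <- tibble::tibble(
    sample = sprintf("S%02d", seq_len(length(lines) * n_rep)),
    line = rep(lines, each = n_rep),
    replicate = rep(seq_len(n_rep), length(lines)))
  eff <- matrix(0, length(genes), length(lines),
                dimnames = list(genes, lines))
  eff[, colnames(effects)] <- effects
  m <- 8 + eff[, match(samples$line, lines)] +
    matrix(rnorm(length(genes) * nrow(samples), sd = noise_sd),
           length(genes))
  colnames(m) <- samples$sample
  expression_set(m, samples)
}
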