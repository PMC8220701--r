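
# Edge-type mixture of the emulated compiled interaction network:
# regulatory, protein-protein and metabolic interaction source counts,
# normalized.
edge_type_proportions <- function() {
  p <- c(regulatory = 64185, ppi = 96827, metabolic = 34003)
  p / sum(p)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  expr
}

#' Default planted group sizes
#'
#' Group-label counts used by [simulate_expression()] when no `labels_spec`
#' is given: the restored/compensatory/non-restored/line-specific group and
#' core sizes of the emulated study, scaled to a quarter (desk scale, 5,000
#' genes).
#'
#' @return List with integer vectors `counts` (labels A-F) and `cores`
#'   (labels A-C).
#' @export
default_labels_spec <- function() {
  list(counts = c(A = 68L, B = 44L, C = 93L, D = 83L, E = 42L, F = 24L),
       cores = c(A = 30L, B = 6L, C = 37L))
}

#' Simulate a five-line expression study with planted group structure
#'
#' Generates log2 intensities for a wild-type reference, a mutant and three
#' suppressor lines with `n_replicates` replicates each.  Per gene `g`,
#' line `l`, replicate `r`: `value = baseline_g + effect(g, l) + noise`,
#' with `noise ~ Normal(0, s_g^2)` and per-gene variances drawn from a
#' scaled inverse chi-square (inverse-gamma) prior so that empirical-Bayes
#' variance moderation is testable.  Planted effects realize the requested
#' group labels exactly under thresholding with ideal power: e.g. a core-A
#' gene is perturbed in the mutant and in no suppressor, a core-B gene in
#' all three suppressors but not the mutant.  Up- and down-regulated
#' effects are planted in equal proportion (the gene score is two-tailed).
#' The reference line always has effect 0.
#'
#' @param n_genes Total number of genes.
#' @param n_replicates Replicates per line.
#' @param labels_spec List with `counts` (named A-F) and `cores` (named
#'   A-C, each at most the corresponding count); see
#'   [default_labels_spec()].
#' @param effect_range Numeric `(lo, hi)` of planted |log2 effect|; `lo`
#'   must exceed `log2(fc_threshold)` or the planted truth would be
#'   undetectable.
#' @param noise List with `d0` (prior degrees of freedom) and `s0_sq`
#'   (prior variance) of the variance prior.
#' @param baseline Mean and sd of the per-gene baseline log2 intensity.
#' @param fc_threshold Fold-change bound the planted effects must clear.
#' @param line_effect_scale Optional named multipliers (per non-reference
#'   line) applied to planted effect magnitudes.  A decreasing gradient
#'   across the suppressor lines emulates negative feedback of signaling
#'   on biosynthesis: hormone-pathway genes are less perturbed in lines
#'   that suppress the mutant phenotype better.  Default: no gradient.
#' @param cfg A [pipeline_config()] supplying the line names.
#' @param rng_seed Integer seed; the same seed reproduces the matrix
#'   bit-identically.
#' @return List with `expr` (an [expression_set()]) and `truth` (a
#'   `synthetic_truth`: tibbles `group_of` and `effect_of`, per-gene noise
#'   sds, `null_params` of the background max-logFC distribution, and the
#'   line roles).
#' @export
simulate_expression <- function(n_genes = 5000L,
                                n_replicates = 3L,
                                labels_spec = default_labels_spec(),
                                effect_range = c(1, 3),
                                noise = list(d0 = 4, s0_sq = 0.04),
                                baseline = c(mean = 7.5, sd = 1.5),
                                fc_threshold = 1.5,
                                line_effect_scale = NULL,
                                cfg = pipeline_config(),
                                rng_seed = 1L) {
  stopifnot(n_replicates >= 2, length(effect_range) == 2,
            effect_range[1] < effect_range[2])
  scale_of <- function(lines) {
    if (is.null(line_effect_scale)) return(rep(1, length(lines)))
    out <- line_effect_scale[lines]
    out[is.na(out)] <- 1
    unname(out)
  }
  min_scale <- if (is.null(line_effect_scale)) 1 else
    min(1, line_effect_scale)
  if (effect_range[1] * min_scale <= log2(fc_threshold)) {
    stop("scaled planted effects fall below log2(fc_threshold): raise ",
         "effect_range or line_effect_scale", call. = FALSE)
  }
  if (effect_range[1] <= log2(fc_threshold)) {
    stop("effect_range lower bound must exceed log2(fc_threshold) = ",
         signif(log2(fc_threshold), 4),
         " or the planted truth is undetectable", call. = FALSE)
  }
  counts <- labels_spec$counts
  cores <- labels_spec$cores
  stopifnot(all(names(cores) %in% names(counts)),
            all(cores <= counts[names(cores)]))
  if (sum(counts) > n_genes) stop("more labeled genes than genes",
                                  call. = FALSE)
  lines <- c(cfg$reference_line, cfg$mutant_line, cfg$suppressor_lines)
  mut <- cfg$mutant_line
  sups <- cfg$suppressor_lines
  genes <- sprintf("AT1G%05d", seq_len(n_genes) * 10)

  with_seed(rng_seed, {
    # assign labels to a random subset of genes
    lab <- rep("none", n_genes)
    core <- rep(FALSE, n_genes)
    pool <- sample.int(n_genes, sum(counts))
    offset <- 0
    for (l in names(counts)) {
      if (counts[[l]] == 0) next
      idx <- pool[(offset + 1):(offset + counts[[l]])]
      lab[idx] <- l
      if (l %in% names(cores) && cores[[l]] > 0) {
        core[idx[seq_len(cores[[l]])]] <- TRUE
      }
      offset <- offset + counts[[l]]
    }

    draw_effect <- function(n) {
      stats::runif(n, effect_range[1], effect_range[2]) *
        sample(c(-1, 1), n, replace = TRUE)
    }
    # per gene: which non-reference lines carry a planted effect
    effects <- list()
    for (i in which(lab != "none")) {
      l <- lab[i]
      de_lines <- switch(
        l,
        A = if (core[i]) mut else c(mut, sample(sups, 1)),
        B = if (core[i]) sups else sample(sups, 2),
        C = if (core[i]) c(mut, sups) else c(mut, sample(sups, 2)),
        D = sups[1], E = sups[2], F = sups[3])
      sgn <- sample(c(-1, 1), 1)
      eff <- abs(draw_effect(length(de_lines))) * sgn * scale_of(de_lines)
      effects[[length(effects) + 1]] <-
        tibble::tibble(gene = genes[i], line = de_lines, effect = eff)
    }
    effect_of <- if (length(effects) > 0) dplyr::bind_rows(effects) else
      tibble::tibble(gene = character(), line = character(),
                     effect = numeric())

    baseline_g <- stats::rnorm(n_genes, baseline[["mean"]],
                               baseline[["sd"]])
    s2 <- noise$s0_sq * noise$d0 / stats::rchisq(n_genes, df = noise$d0)
    sds <- sqrt(s2)

    sample_tbl <- tibble::tibble(
      sample = paste0("S", sprintf(
        "%02d", seq_len(length(lines) * n_replicates))),
      line = rep(lines, each = n_replicates),
      replicate = rep(seq_len(n_replicates), times = length(lines)))
    eff_mat <- matrix(0, n_genes, length(lines),
                      dimnames = list(genes, lines))
    if (nrow(effect_of) > 0) {
      eff_mat[cbind(match(effect_of$gene, genes),
                    match(effect_of$line, lines))] <- effect_of$effect
    }
    m <- matrix(stats::rnorm(n_genes * nrow(sample_tbl)), n_genes) * sds +
      baseline_g + eff_mat[, match(sample_tbl$line, lines)]
    colnames(m) <- sample_tbl$sample

    null_params <- simulate_null_params(noise, n_replicates,
                                        n_lines = length(lines) - 1)

    truth <- structure(list(
      group_of = tibble::tibble(gene = genes, label = factor(
        lab, levels = c("A", "B", "C", "D", "E", "F", "none")),
        core = core),
      effect_of = effect_of,
      noise_sd = tibble::tibble(gene = genes, sd = sds),
      null_params = null_params,
      lines = list(reference = cfg$reference_line, mutant = mut,
                   suppressors = sups),
      planted_modules = list(),
      module_seeds = character(0)),
      class = "synthetic_truth")
    list(expr = expression_set(m, sample_tbl), truth = truth)
  })
}

# Monte-Carlo moments of the background (no planted effect) selected
# max-logFC: per gene the logFC of largest absolute value across the
# non-reference lines.  All contrasts share the same reference replicate
# mean, so the per-line logFCs are positively correlated; the simulation
# reproduces that structure.
simulate_null_params <- function(noise, n_replicates, n_lines,
                                 n_sim = 50000L) {
  s2 <- noise$s0_sq * noise$d0 / stats::rchisq(n_sim, df = noise$d0)
  se <- sqrt(s2 / n_replicates)
  ref <- stats::rnorm(n_sim) * se
  fc <- matrix(stats::rnorm(n_sim * n_lines), n_sim) * se - ref
  pick <- max.col(abs(fc), ties.method = "first")
  x <- fc[cbind(seq_len(n_sim), pick)]
  c(mu = mean(x), sigma = stats::sd(x))
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>\n")
  print(dplyr::count(x$group_of, .data$label, .drop = FALSE))
  cat(sprintf("  %d planted module(s); null mu = %.4g, sigma = %.4g\n",
              length(x$planted_modules), x$null_params[["mu"]],
              x$null_params[["sigma"]]))
  invisible(x)
}

#' Simulate an interaction network with planted modules
#'
#' Builds a degree-biased random background graph (preferential attachment)
#' over all genes plus optional extra connector-pool genes, then wires each
#' planted module as a connected regulon: the module's first seed gene acts
#' as a master regulator wired to every other member (seed genes are drawn
#' from the planted differentially expressed groups A-C), 1-2 members are
#' instead reached through a non-DE connector gene (emulating connector
#' genes such as signaling proteins that are not themselves differentially
#' expressed), and extra member-member edges are added with probability
#' `module_bias`.  All internal seed-to-seed paths have at most 4 edges and
#' pass through 0-2 connectors.  Edge types (regulatory / ppi / metabolic)
#' are assigned at the proportions of the emulated compiled network;
#' directed module edges are oriented downstream from the regulator, ppi
#' edges are undirected, background directed edges get a random
#' orientation.
#'
#' @param truth A `synthetic_truth` from [simulate_expression()].
#' @param n_background_nodes Extra connector-pool genes absent from the
#'   expression data.
#' @param background_degree Target average degree of the background graph
#'   (preferential attachment with `background_degree / 2` edges per node).
#' @param n_modules Number of planted modules.
#' @param module_size Integer range of seed genes per module.
#' @param module_bias Probability of an extra direct edge between two
#'   module member genes.  The default plants a clean regulon (0): denser
#'   within-module wiring creates many alternative minimal covers, which
#'   makes the parsimonious selection ambiguous and can split the
#'   recovered component.
#' @param path_length Bound the module wiring must respect (internal paths
#'   of at most this many edges).
#' @param rng_seed Integer seed.
#' @return List with `network` (a `gene_network`) and `truth` (updated with
#'   `planted_modules`, each a list with `genes` and `edges`, and
#'   `module_seeds`).
#' @export
simulate_network <- function(truth,
                             n_background_nodes = 0L,
                             background_degree = 8,
                             n_modules = 3L,
                             module_size = c(15L, 25L),
                             module_bias = 0,
                             path_length = 4L,
                             rng_seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (path_length < 3 && n_modules > 0) {
    stop("module wiring needs path_length >= 3 (seed-connector-connector-",
         "seed paths)", call. = FALSE)
  }
  props <- edge_type_proportions()
  genes <- truth$group_of$gene
  extra <- if (n_background_nodes > 0)
    sprintf("CONNECT%05d", seq_len(n_background_nodes)) else character(0)
  all_nodes <- c(genes, extra)
  m_pa <- max(1L, round(background_degree / 2))

  with_seed(rng_seed, {
    g <- igraph::sample_pa(length(all_nodes), m = m_pa, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    perm <- sample(all_nodes)
    bg <- tibble::tibble(source = perm[el[, 1]], target = perm[el[, 2]],
                         type = sample(names(props), nrow(el),
                                       replace = TRUE, prob = props))
    # random orientation for directed types
    flip <- bg$type != "ppi" & stats::runif(nrow(bg)) < 0.5
    tmp <- bg$source[flip]
    bg$source[flip] <- bg$target[flip]
    bg$target[flip] <- tmp

    de_pool <- truth$group_of$gene[truth$group_of$label %in% c("A", "B",
                                                               "C")]
    none_pool <- truth$group_of$gene[truth$group_of$label == "none"]
    sizes <- sample(seq(module_size[1], module_size[2]), n_modules,
                    replace = TRUE)
    if (sum(sizes) > length(de_pool)) {
      stop("not enough planted DE genes for the requested modules",
           call. = FALSE)
    }
    seeds_all <- sample(de_pool, sum(sizes))
    conn_pool <- sample(none_pool, 2 * n_modules)
    # the planted wiring alone defines the structure among module seed
    # genes: coincidental background edges between two module seeds would
    # make the planted truth unidentifiable, so they are removed
    bg <- bg[!(bg$source %in% seeds_all & bg$target %in% seeds_all), ]
    modules <- list()
    mod_edges_all <- list()
    offset <- 0
    for (mi in seq_len(n_modules)) {
      seeds <- seeds_all[(offset + 1):(offset + sizes[mi])]
      offset <- offset + sizes[mi]
      # regulon wiring: the first seed acts as the module's master
      # regulator (hub); every other member is wired to it, so all
      # internal seed-to-seed paths share the hub (<= 2 edges, diameter
      # <= 4 with connectors)
      hub <- seeds[1]
      members <- seeds[-1]
      # 1-2 internal paths run through a non-DE connector gene: the
      # connector mediates hub -> member for one member, which then has
      # no direct hub edge
      n_conn <- sample(1:2, 1)
      conns <- conn_pool[(2 * mi - 1):(2 * mi)][seq_len(n_conn)]
      via_conn <- members[seq_len(n_conn)]
      direct_members <- setdiff(members, via_conn)
      e <- dplyr::bind_rows(
        tibble::tibble(source = hub, target = direct_members),
        tibble::tibble(source = hub, target = conns),
        tibble::tibble(source = conns, target = via_conn))
      # extra within-pathway interactions between module members
      pairs <- utils::combn(members, 2)
      direct <- stats::runif(ncol(pairs)) < module_bias
      if (any(direct)) {
        e <- dplyr::bind_rows(e, tibble::tibble(
          source = pairs[1, direct], target = pairs[2, direct]))
      }
      # directed interaction types flow downstream from the regulator
      e$type <- sample(names(props), nrow(e), replace = TRUE, prob = props)
      modules[[mi]] <- list(genes = sort(c(seeds, conns)),
                            seeds = sort(seeds), connectors = conns,
                            edges = as_gene_network(e))
      mod_edges_all[[mi]] <- e
    }
    network <- as_gene_network(dplyr::bind_rows(bg, mod_edges_all))
    truth$planted_modules <- modules
    truth$module_seeds <- sort(unlist(lapply(modules, `[[`, "seeds"),
                                      use.names = FALSE))
    list(network = network, truth = truth)
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: [simulate_expression()] followed by
#' [simulate_network()], with the network seed derived from `rng_seed`.
#'
#' @param cfg A [pipeline_config()].
#' @param n_genes,n_modules,module_size Scenario scale.
#' @param rng_seed Integer seed.
#' @param ... Passed on to [simulate_expression()].
#' @return List with `expr`, `truth`, `network`.
#' @export
simulate_study <- function(cfg = pipeline_config(), n_genes = 5000L,
                           n_modules = 3L, module_size = c(15L, 25L),
                           rng_seed = cfg$rng_seed, ...) {
  sim <- simulate_expression(n_genes = n_genes, cfg = cfg,
                             rng_seed = rng_seed, ...)
  net <- simulate_network(sim$truth, n_modules = n_modules,
                          module_size = module_size,
                          path_length = cfg$path_length,
                          rng_seed = rng_seed + 10000L)
  list(expr = sim$expr, truth = net$truth, network = net$network)
}
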