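
# ---- internal machinery ------------------------------------------------

# Undirected edge identity used for size counting, Jaccard and components:
# (min endpoint, max endpoint, type).
edge_ukey <- function(edges) {
  paste(pmin(edges$source, edges$target),
        pmax(edges$source, edges$target),
        edges$type, sep = "\r")
}

# Expand a typed edge table into directed arcs: regulatory and metabolic
# edges give one arc source -> target, ppi edges give both directions.
expand_arcs <- function(network, node_index) {
  src <- node_index[network$source]
  tgt <- node_index[network$target]
  undir <- network$type == "ppi"
  from <- c(src, tgt[undir])
  to <- c(tgt, src[undir])
  edge <- c(seq_len(nrow(network)), which(undir))
  o <- order(from, to, edge)
  list(from = from[o], to = to[o], edge = edge[o])
}

# Enumerate every simple path of <= max_len edges between seed nodes.
# Penalty-independent: per-path edge lists are enumerated once (stored
# flat) and costs are attached later for each penalty in the sweep.
prepare_paths <- function(network, seeds, max_len,
                          max_paths = 5e6, max_steps = 5e8) {
  nodes <- sort(unique(c(network$source, network$target)))
  node_index <- stats::setNames(seq_along(nodes), nodes)
  missing <- setdiff(seeds, nodes)
  if (length(missing) > 0) {
    message("skipping ", length(missing),
            " seed(s) absent from the network: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "")
    seeds <- setdiff(seeds, missing)
  }
  seeds <- sort(seeds)
  arcs <- expand_arcs(network, node_index)
  is_target <- rep(FALSE, length(nodes))
  is_target[node_index[seeds]] <- TRUE
  res <- enumerate_seed_paths_cpp(
    arc_from = arcs$from - 1L, arc_to = arcs$to - 1L,
    arc_edge = arcs$edge - 1L, n_nodes = length(nodes),
    sources = unname(node_index[seeds]) - 1L, is_target = is_target,
    max_len = as.integer(max_len), max_paths = max_paths,
    max_steps = max_steps)
  len <- res$len
  n_paths <- length(len)
  flat_nodes <- res$nodes + 1L
  flat_edges <- res$edges + 1L
  node_off <- c(0L, cumsum(len + 1L))[seq_len(n_paths)] + 1L
  edge_off <- c(0L, cumsum(len))[seq_len(n_paths)] + 1L
  first <- flat_nodes[node_off]
  last <- flat_nodes[node_off + len]
  # lexicographic rank of the node sequences (node indices follow the
  # sorted node names, so integer order equals lexicographic ID order);
  # simple paths are distinct sequences, hence ranks are unique
  key_rank <- integer(n_paths)
  if (n_paths > 0) {
    mat <- matrix(0L, n_paths, max_len + 1L)
    mat[cbind(rep(seq_len(n_paths), len + 1L), sequence(len + 1L))] <-
      flat_nodes
    ord <- do.call(order, as.data.frame(mat))
    key_rank[ord] <- seq_len(n_paths)
  }
  sum1mw <- numeric(0)
  if (n_paths > 0) {
    grp <- rep(seq_len(n_paths), len)
    sum1mw <- as.vector(rowsum((1 - network$weight)[flat_edges], grp))
  }
  ukeys <- edge_ukey(network)
  list(network = network, nodes = nodes, node_index = node_index,
       seeds = seeds, n_paths = n_paths,
       flat_nodes = flat_nodes, node_off = node_off,
       flat_edges = flat_edges, edge_off = edge_off,
       first = first, last = last, len = len,
       sum1mw = sum1mw, key_rank = key_rank,
       ukey = ukeys, ukey_id = match(ukeys, unique(ukeys)))
}

# Flat edge-index arrays for a candidate subset, reusable across the
# stability resamples of one penalty.
candidate_flat <- function(prep, cand) {
  lens <- prep$len[cand]
  flat <- if (length(cand) > 0) {
    prep$flat_edges[sequence(lens, from = prep$edge_off[cand])]
  } else integer(0)
  list(first = prep$first[cand], last = prep$last[cand],
       lens = lens, flat = flat,
       off = c(0L, cumsum(lens)))
}

# Run the compiled greedy on a candidate set with a given active seed set.
run_greedy <- function(prep, cf, edge_costs, active_seed_nodes) {
  active <- rep(FALSE, length(prep$nodes))
  active[active_seed_nodes] <- TRUE
  res <- greedy_select_cpp(cf$first - 1L, cf$last - 1L, cf$flat - 1L,
                           cf$lens, edge_costs, active,
                           length(prep$nodes))
  list(edges = res$edges, connected = res$connected,
       paths = res$paths, score = res$score)
}
# Indices (into the prepared path table) of the k best paths per ordered
# seed pair at penalty c: ordered by (cost, fewer edges, lexicographic
# node sequence).
k_best_index <- function(prep, penalty_c, k, eps = 1e-3) {
  if (prep$n_paths == 0) return(integer(0))
  cost <- penalty_c * prep$sum1mw + prep$len * eps
  pair <- prep$first * (length(prep$nodes) + 1) + prep$last
  o <- order(pair, cost, prep$len, prep$key_rank)
  pos <- stats::ave(seq_along(o), pair[o], FUN = seq_along)
  sel <- o[pos <= k]
  # canonical global order so that greedy tie-breaks are deterministic
  sel[order(cost[sel], prep$len[sel], prep$key_rank[sel])]
}

jaccard <- function(a, b) {
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

mean_pairwise_jaccard <- function(sets) {
  n <- length(sets)
  if (n < 2) return(1)
  pairs <- utils::combn(n, 2)
  mean(apply(pairs, 2, function(ij) jaccard(sets[[ij[1]]], sets[[ij[2]]])))
}

# ---- exported operations ----------------------------------------------

#' Bounded k-best path search from one seed
#'
#' Enumerates, for each reachable target seed, the `k` lowest-cost simple
#' paths with at most `max_len` edges that start at `seed`, following
#' directed edges only source to target (downstream mode) and ppi edges in
#' either direction.  Ties are broken by fewer edges, then by the
#' lexicographic node sequence.  Edge costs are
#' `penalty_c * (1 - weight) + eps` (see [edge_cost()]); a `weight` column
#' on the network is required.
#'
#' @param network A `gene_network` tibble with a `weight` column.
#' @param seed Seed gene (path start).  Absent from the network: logged and
#'   an empty result returned.
#' @param target_seeds Target seed genes.
#' @param k Paths retained per target.
#' @param max_len Maximum number of edges per path.
#' @param penalty_c Edge penalty.
#' @param eps Positivity floor of the cost function.
#' @return Tibble with columns `source`, `target`, `cost`, `n_edges`,
#'   `nodes` (list of node-ID vectors) and `edges` (list of undirected edge
#'   keys `u\\rv\\rtype`).
#' @export
k_best_paths <- function(network, seed, target_seeds, k = 50L,
                         max_len = 4L, penalty_c = 1, eps = 1e-3) {
  empty <- tibble::tibble(source = character(), target = character(),
                          cost = numeric(), n_edges = integer(),
                          nodes = list(), edges = list())
  nodes_all <- unique(c(network$source, network$target))
  if (!seed %in% nodes_all) {
    message("seed absent from the network, skipped: ", seed)
    return(empty)
  }
  seeds <- unique(c(seed, intersect(target_seeds, nodes_all)))
  prep <- prepare_paths(network, seeds, max_len)
  if (prep$n_paths == 0) return(empty)
  from_seed <- prep$first == prep$node_index[[seed]] &
    prep$nodes[prep$last] %in% target_seeds
  idx <- which(from_seed)
  if (length(idx) == 0) return(empty)
  cost <- penalty_c * prep$sum1mw[idx] + prep$len[idx] * eps
  node_list <- lapply(idx, function(i) {
    prep$nodes[prep$flat_nodes[prep$node_off[i] + 0:prep$len[i]]]
  })
  edge_list <- lapply(idx, function(i) {
    prep$ukey[prep$flat_edges[prep$edge_off[i] + seq_len(prep$len[i]) - 1L]]
  })
  tab <- tibble::tibble(
    source = seed,
    target = prep$nodes[prep$last[idx]],
    cost = cost,
    n_edges = prep$len[idx],
    nodes = node_list,
    edges = edge_list,
    .rank = prep$key_rank[idx]
  )
  tab <- tab %>%
    dplyr::arrange(.data$target, .data$cost, .data$n_edges, .data$.rank) %>%
    dplyr::group_by(.data$target) %>%
    dplyr::slice_head(n = k) %>%
    dplyr::ungroup() %>%
    dplyr::select(-".rank")
  tab
}

#' Greedy parsimonious subnetwork selection
#'
#' Pools candidate paths between seed pairs and repeatedly adds the path
#' with the best ratio of newly connected seeds to the cost of its not yet
#' selected edges, until no remaining path connects a new seed.  The
#' selection score is the number of connected seeds minus the total cost of
#' the selected edges.
#'
#' @param paths Candidate tibble as produced by [k_best_paths()] (columns
#'   `source`, `target`, `cost`, `edges`).  Row order is the tie-break
#'   order: among equal ratios the earliest row wins, so pass candidates
#'   sorted by (cost, fewer edges, lexicographic node sequence).
#' @param seeds Seed genes eligible for connection.
#' @param edge_costs Named numeric vector: cost per undirected edge key.
#' @return List of class `subnetwork`: `edges` (character vector of edge
#'   keys), `connected_seeds`, `selection_score`, `n_edges`.
#' @export
select_subnetwork <- function(paths, seeds, edge_costs) {
  out <- list(edges = character(0), connected_seeds = character(0),
              selection_score = 0, n_edges = 0L)
  class(out) <- "subnetwork"
  if (nrow(paths) == 0) return(out)
  keep <- paths$source %in% seeds & paths$target %in% seeds
  paths <- paths[keep, , drop = FALSE]
  if (nrow(paths) == 0) return(out)
  bad <- setdiff(unique(unlist(paths$edges)), names(edge_costs))
  if (length(bad) > 0) {
    stop("path edge(s) missing from `edge_costs`: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  node_ids <- sort(unique(c(paths$source, paths$target)))
  keys <- names(edge_costs)
  flat <- match(unlist(paths$edges), keys)
  lens <- lengths(paths$edges)
  active <- node_ids %in% seeds
  res <- greedy_select_cpp(match(paths$source, node_ids) - 1L,
                           match(paths$target, node_ids) - 1L,
                           flat - 1L, lens, unname(edge_costs), active,
                           length(node_ids))
  out$edges <- sort(keys[res$edges])
  out$connected_seeds <- sort(node_ids[res$connected])
  out$selection_score <- res$score
  out$n_edges <- length(out$edges)
  out
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("<subnetwork> %d edges, %d connected seeds, score %.4g\n",
              x$n_edges, length(x$connected_seeds), x$selection_score))
  invisible(x)
}

#' Stability of subnetwork selection at one penalty
#'
#' Repeats the greedy selection on random subsets of the seeds (jackknife
#' ensemble: `resamples` draws of `ceiling(fraction * n_seeds)` seeds) and
#' returns the mean pairwise Jaccard index of the selected undirected edge
#' sets.  Selections supported by shared structure (paths overlapping in
#' common hubs) survive resampling; selections built from seed-pair
#' exclusive paths dilute under it and are rejected by the sweep's
#' stability bound.  Two empty edge sets count as identical (Jaccard 1).
#'
#' @param network A `gene_network` with a `weight` column.
#' @param seeds Seed genes.
#' @param penalty_c Edge penalty.
#' @param resamples Number of seed subsamples (>= 2).
#' @param fraction Fraction of seeds kept per subsample.
#' @param rng_seed Integer seed for the subsampling.
#' @param k,max_len,eps Path-search parameters, see [k_best_paths()].
#' @return Stability in \[0, 1\].
#' @export
subnetwork_stability <- function(network, seeds, penalty_c,
                                 resamples = 10L, fraction = 0.8,
                                 rng_seed = 1L, k = 50L, max_len = 4L,
                                 eps = 1e-3) {
  stopifnot(resamples >= 2)
  prep <- prepare_paths(network, seeds, max_len)
  cand <- k_best_index(prep, penalty_c, k, eps)
  cf <- candidate_flat(prep, cand)
  edge_costs <- edge_cost(network$weight, penalty_c, eps)
  stability_from_prep(prep, cf, edge_costs, resamples, fraction, rng_seed)
}

# Selection stability under seed jackknifing: plain mean pairwise Jaccard
# of the undirected edge sets selected on resampled seed subsets.
stability_from_prep <- function(prep, cf, edge_costs, resamples,
                                fraction, rng_seed) {
  seeds <- prep$seeds
  m <- ceiling(fraction * length(seeds))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  set.seed(rng_seed)
  sets <- lapply(seq_len(resamples), function(r) {
    sub <- sample(seeds, m)
    sel <- run_greedy(prep, cf, edge_costs, unname(prep$node_index[sub]))
    sort(unique(prep$ukey_id[sel$edges]))
  })
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  mean_pairwise_jaccard(sets)
}

#' Penalty sweep, stability filtering and final subnetworks
#'
#' The full inference engine: for each of `cost_steps` log-spaced penalties
#' between `cost_min` and `cost_max` it builds the k-best bounded candidate
#' paths between all seed pairs, greedily selects the highest-scoring
#' subnetwork, and measures its stability.  A penalty's subnetwork is
#' rejected when its stability is below `jaccard_min` or it exceeds
#' `max_edges` unique undirected edges.  The final result is the union of
#' all accepted edge sets, decomposed (direction-blind) into connected
#' components reported as separate subnetworks; non-seed members are
#' flagged as connector genes.
#'
#' @param network A `gene_network` with a `weight` column (see
#'   [score_network()]).
#' @param seeds Seed genes to connect.
#' @param cfg A [pipeline_config()] supplying the sweep parameters.
#' @param scores Optional gene-score tibble (`gene`, `score`) used to
#'   annotate the node table; genes absent from it get score 0.
#' @param groups Optional [classify_groups()] output used to annotate the
#'   node table with group labels and core flags.
#' @return Object of class `subnetwork_set`: list with `nodes`, `edges`
#'   (per-component tibbles), `components` (per-component summary), `sweep`
#'   (per-penalty diagnostics) and `seeds`.
#' @export
infer_subnetworks <- function(network, seeds, cfg = pipeline_config(),
                              scores = NULL, groups = NULL) {
  validate_config(cfg)
  if (!"weight" %in% names(network)) {
    stop("network needs a `weight` column; see score_network()",
         call. = FALSE)
  }
  prep <- prepare_paths(network, seeds, cfg$path_length)
  grid <- penalty_grid(cfg)
  eps <- 1e-3
  sweep <- vector("list", length(grid))
  accepted_ukeys <- integer(0)
  for (i in seq_along(grid)) {
    cc <- grid[i]
    cand <- k_best_index(prep, cc, cfg$k_paths, eps)
    cf <- candidate_flat(prep, cand)
    edge_costs <- edge_cost(network$weight, cc, eps)
    sel <- run_greedy(prep, cf, edge_costs,
                      unname(prep$node_index[prep$seeds]))
    ukeys <- sort(unique(prep$ukey_id[sel$edges]))
    stab <- stability_from_prep(prep, cf, edge_costs, cfg$resamples,
                                cfg$fraction, cfg$rng_seed + i)
    ok <- stab >= cfg$jaccard_min && length(ukeys) <= cfg$max_edges
    if (ok) accepted_ukeys <- union(accepted_ukeys, ukeys)
    sweep[[i]] <- tibble::tibble(
      penalty = cc, n_candidates = length(cand),
      n_edges = length(ukeys),
      n_connected_seeds = length(intersect(
        prep$nodes[sel$connected], prep$seeds)),
      selection_score = sel$score, stability = stab, accepted = ok)
  }
  sweep <- dplyr::bind_rows(sweep)
  if (length(accepted_ukeys) == 0) {
    warning("no penalty yielded a stable non-empty subnetwork; ",
            "empty result", call. = FALSE)
  }
  # one representative edge row per accepted undirected edge
  rep_rows <- which(!duplicated(prep$ukey_id))
  rep_rows <- rep_rows[prep$ukey_id[rep_rows] %in% accepted_ukeys]
  edges <- network[rep_rows, , drop = FALSE]
  nodes_in <- sort(unique(c(edges$source, edges$target)))
  if (length(nodes_in) > 0) {
    g <- igraph::graph_from_data_frame(
      edges[, c("source", "target")], directed = FALSE,
      vertices = nodes_in)
    comp <- igraph::components(g)
    memb <- comp$membership
    # deterministic component ids: by size desc, then smallest member name
    info <- tibble::tibble(old = seq_len(comp$no),
                           size = as.integer(comp$csize),
                           min_node = vapply(seq_len(comp$no), function(ci)
                             min(names(memb)[memb == ci]), character(1)))
    info <- dplyr::arrange(info, dplyr::desc(.data$size), .data$min_node)
    relabel <- stats::setNames(seq_len(nrow(info)), info$old)
    node_comp <- unname(relabel[as.character(memb[nodes_in])])
  } else {
    node_comp <- integer(0)
  }
  nodes <- tibble::tibble(
    gene = nodes_in,
    component = node_comp,
    is_seed = nodes_in %in% prep$seeds,
    connector = !(nodes_in %in% prep$seeds),
    score = 0
  )
  if (!is.null(scores)) {
    sc <- stats::setNames(scores$score, scores$gene)
    hit <- nodes$gene %in% names(sc)
    nodes$score[hit] <- unname(sc[nodes$gene[hit]])
  }
  nodes$label <- factor("none",
                        levels = c("A", "B", "C", "D", "E", "F", "none"))
  nodes$core <- FALSE
  if (!is.null(groups)) {
    gi <- match(nodes$gene, groups$gene)
    hit <- !is.na(gi)
    nodes$label[hit] <- groups$label[gi[hit]]
    nodes$core[hit] <- groups$core[gi[hit]]
  }
  edges$component <- nodes$component[match(edges$source, nodes$gene)]
  nodes <- dplyr::arrange(nodes, .data$component, .data$gene)
  edges <- dplyr::arrange(edges, .data$component, .data$source,
                          .data$target)
  components <- nodes %>%
    dplyr::group_by(.data$component) %>%
    dplyr::summarise(n_nodes = dplyr::n(),
                     n_seeds = sum(.data$is_seed),
                     n_connectors = sum(.data$connector),
                     .groups = "drop") %>%
    dplyr::left_join(dplyr::count(edges, .data$component, name = "n_edges"),
                     by = "component")
  structure(list(nodes = nodes, edges = edges, components = components,
                 sweep = sweep, seeds = prep$seeds),
            class = "subnetwork_set")
}

#' @export
print.subnetwork_set <- function(x, ...) {
  cat(sprintf(
    "<subnetwork_set> %d component(s), %d nodes (%d seeds, %d connectors), %d edges\n",
    nrow(x$components), nrow(x$nodes), sum(x$nodes$is_seed),
    sum(x$nodes$connector), nrow(x$edges)))
  cat(sprintf("  %d/%d penalties accepted\n", sum(x$sweep$accepted),
              nrow(x$sweep)))
  invisible(x)
}

#' @export
tidy.subnetwork_set <- function(x, ...) {
  x$nodes[, c("gene", "component", "label", "core", "connector", "score")]
}

#' @export
glance.subnetwork_set <- function(x, ...) {
  tibble::tibble(
    n_components = nrow(x$components),
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_connected_seeds = sum(x$nodes$is_seed),
    n_seeds = length(x$seeds),
    n_accepted_penalties = sum(x$sweep$accepted))
}

#' Planted-module recovery metrics
#'
#' Matches each planted module to the final component with the largest node
#' overlap and reports precision, recall and F1 at the node and undirected
#' edge level.  With no recovered component, recall is 0.
#'
#' @param subnetworks A `subnetwork_set` from [infer_subnetworks()].
#' @param truth A `synthetic_truth` carrying `planted_modules`.
#' @return Tibble: one row per planted module with the matched component
#'   and the six metrics.
#' @export
recover_planted <- function(subnetworks, truth) {
  modules <- truth$planted_modules
  nodes <- subnetworks$nodes
  edges <- subnetworks$edges
  purrr::map_dfr(seq_along(modules), function(i) {
    mod <- modules[[i]]
    overlaps <- vapply(
      sort(unique(nodes$component)),
      function(ci) length(intersect(nodes$gene[nodes$component == ci],
                                    mod$genes)), integer(1))
    if (length(overlaps) == 0 || max(overlaps) == 0) {
      return(tibble::tibble(
        module = i, component = NA_integer_,
        n_module = length(mod$genes), n_component = 0L,
        node_precision = NA_real_, node_recall = 0, node_f1 = 0,
        edge_precision = NA_real_, edge_recall = 0, edge_f1 = 0))
    }
    ci <- sort(unique(nodes$component))[which.max(overlaps)]
    comp_nodes <- nodes$gene[nodes$component == ci]
    np <- length(intersect(comp_nodes, mod$genes)) / length(comp_nodes)
    nr <- length(intersect(comp_nodes, mod$genes)) / length(mod$genes)
    nf <- if (np + nr > 0) 2 * np * nr / (np + nr) else 0
    comp_e <- edge_ukey(edges[edges$component == ci, , drop = FALSE])
    mod_e <- edge_ukey(mod$edges)
    ep <- if (length(comp_e) > 0)
      length(intersect(comp_e, mod_e)) / length(comp_e) else NA_real_
    er <- if (length(mod_e) > 0)
      length(intersect(comp_e, mod_e)) / length(mod_e) else NA_real_
    ef <- if (!is.na(ep) && !is.na(er) && ep + er > 0)
      2 * ep * er / (ep + er) else 0
    tibble::tibble(module = i, component = ci,
                   n_module = length(mod$genes),
                   n_component = length(comp_nodes),
                   node_precision = np, node_recall = nr, node_f1 = nf,
                   edge_precision = ep, edge_recall = er, edge_f1 = ef)
  })
}
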