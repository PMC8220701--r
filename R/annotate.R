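#' Hypergeometric gene-set over-representation
#'
#' For each term with at least one member in the universe, tests whether the
#' query is enriched for the term: with `N` universe genes, `K` term genes,
#' `n` query genes and `k` of the query in the term, the p-value is the
#' hypergeometric upper tail `P(X >= k)`.  P-values are adjusted across
#' terms with [bh_adjust()].
#'
#' @param query Character vector of query genes; must be a subset of
#'   `universe`.
#' @param annotations Named list mapping term to member genes (e.g. from
#'   [read_annotations()] or [read_gene_sets()]); members outside the
#'   universe are ignored.
#' @param universe Character vector defining the gene universe (typically
#'   all genes on the expression matrix).
#' @return Tibble with columns `term`, `k`, `K`, `n`, `N`, `p`, `adj_p`,
#'   sorted by `p`.
#' @examples
#' hypergeom_enrich(c("g1", "g2"), list(T1 = c("g1", "g2", "g3")),
#'                  paste0("g", 1:10))
#' @export
hypergeom_enrich <- function(query, annotations, universe) {
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    stop("query gene(s) outside the universe: ",
         paste(utils::head(outside, 10), collapse = ", "),
         if (length(outside) > 10) ", ..." else "", call. = FALSE)
  }
  N <- length(universe)
  n <- length(query)
  sets <- lapply(annotations, function(g) intersect(unique(g), universe))
  sets <- sets[lengths(sets) > 0]
  out <- purrr::map_dfr(names(sets), function(term) {
    K <- length(sets[[term]])
    k <- length(intersect(query, sets[[term]]))
    tibble::tibble(term = term, k = k, K = K, n = n, N = N,
                   p = stats::phyper(k - 1, K, N - K, n,
                                     lower.tail = FALSE))
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(term = character(), k = integer(), K = integer(),
                          n = integer(), N = integer(), p = numeric(),
                          adj_p = numeric()))
  }
  out$adj_p <- bh_adjust(out$p)
  dplyr::arrange(out, .data$p, .data$term)
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Compares group means with a one-way ANOVA and all pairwise Tukey HSD
#' tests (studentized range), then summarizes the pairwise pattern as a
#' compact letter display: groups sharing a letter are not significantly
#' different at `alpha`.  Letters are assigned from the highest mean down,
#' so "a" always marks the group(s) with the highest mean.
#'
#' @param data Data frame with the value and group columns.
#' @param value,group Column names (strings) of the measurements and the
#'   grouping factor.
#' @param alpha Significance level for the letter display.
#' @return Object of class `tukey_cld`: list with `means` (per group: mean,
#'   n, letters), `pairwise` (Tukey-adjusted pairwise p-values) and `anova`
#'   (F statistic, degrees of freedom, p).
#' @examples
#' d <- data.frame(y = c(rnorm(5), rnorm(5, 10)),
#'                 g = rep(c("a", "b"), each = 5))
#' anova_tukey_cld(d, "y", "g")
#' @export
anova_tukey_cld <- function(data, value = "value", group = "group",
                            alpha = 0.05) {
  df <- tibble::tibble(value = data[[value]],
                       group = as.character(data[[group]]))
  sizes <- table(df$group)
  if (length(sizes) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2)) {
    stop("every group needs at least 2 values; offending group(s): ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  df$group <- factor(df$group)
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tuk <- stats::TukeyHSD(fit)$group
  cmp <- strsplit(rownames(tuk), "-", fixed = TRUE)
  pairwise <- tibble::tibble(
    group1 = vapply(cmp, `[[`, character(1), 1L),
    group2 = vapply(cmp, `[[`, character(1), 2L),
    diff = unname(tuk[, "diff"]),
    adj_p = unname(tuk[, "p adj"]))
  means <- df %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(mean = mean(.data$value), n = dplyr::n(),
                     .groups = "drop") %>%
    dplyr::mutate(group = as.character(.data$group)) %>%
    dplyr::arrange(dplyr::desc(.data$mean))
  means$letters <- cld_letters(means$group, pairwise, alpha)
  structure(list(means = means, pairwise = pairwise,
                 anova = tibble::tibble(
                   statistic = an[["F value"]][1],
                   df1 = an[["Df"]][1], df2 = an[["Df"]][2],
                   p = an[["Pr(>F)"]][1])),
            class = "tukey_cld")
}

# Compact letter display: letters are the maximal cliques of the
# non-significance graph, ordered by the highest member mean (groups must
# arrive ordered by decreasing mean).
cld_letters <- function(groups_desc, pairwise, alpha) {
  k <- length(groups_desc)
  adj <- matrix(TRUE, k, k, dimnames = list(groups_desc, groups_desc))
  for (i in seq_len(nrow(pairwise))) {
    if (pairwise$adj_p[i] < alpha) {
      g1 <- pairwise$group1[i]; g2 <- pairwise$group2[i]
      adj[g1, g2] <- adj[g2, g1] <- FALSE
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  cliques <- igraph::max_cliques(g)
  members <- lapply(cliques, function(cl) sort(match(names(cl),
                                                     groups_desc)))
  ord <- order(vapply(members, min, integer(1)),
               vapply(members, function(m) paste(m, collapse = ","),
                      character(1)))
  members <- members[ord]
  letts <- vapply(seq_along(groups_desc), function(i) {
    paste(letters[which(vapply(members, function(m) i %in% m, logical(1)))],
          collapse = "")
  }, character(1))
  letts
}

#' @export
print.tukey_cld <- function(x, ...) {
  cat(sprintf("<tukey_cld> F(%d, %d) = %.4g, p = %.3g\n",
              x$anova$df1, x$anova$df2, x$anova$statistic, x$anova$p))
  print(x$means)
  invisible(x)
}

#' @export
tidy.tukey_cld <- function(x, ...) x$pairwise

#' @export
glance.tukey_cld <- function(x, ...) x$anova

#' Feedback trend between phenotypic suppression and expression change
#'
#' Tests whether a gene set (e.g. hormone-biosynthesis genes) is less
#' perturbed in lines that better restore the wild-type phenotype.  For
#' each line of `line_ranking` (ordered best to worst suppression) the mean
#' `|logFC|` over the gene set is computed; the statistic is the Spearman
#' rank correlation between the suppression rank and the mean `|logFC|`,
#' with an exact permutation p-value over all line-label permutations
#' (one-sided, `rho_perm >= rho_obs`).  Constant means make the correlation
#' undefined: it is reported as 0 with `degenerate = TRUE`.
#'
#' @param de A `de_table`.
#' @param genes Gene set (genes absent from the DE table are logged and
#'   skipped).
#' @param line_ranking Lines ordered from best to worst phenotypic
#'   suppression.
#' @return List of class `feedback_trend`: `per_line` tibble (line, rank,
#'   mean_abs_logfc, n_genes), `rho`, `p_value`, `degenerate`.
#' @export
feedback_trend <- function(de, genes, line_ranking) {
  present <- intersect(genes, unique(de$gene))
  missing <- setdiff(genes, present)
  if (length(missing) > 0) {
    message("skipping ", length(missing),
            " gene(s) absent from the DE table: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "")
  }
  if (length(present) == 0) stop("no gene left to test", call. = FALSE)
  if (length(line_ranking) > 8) {
    stop("exact permutation test supports at most 8 lines", call. = FALSE)
  }
  per_line <- purrr::map_dfr(seq_along(line_ranking), function(i) {
    sub <- de[de$line == line_ranking[i] & de$gene %in% present, ]
    tibble::tibble(line = line_ranking[i], rank = i,
                   mean_abs_logfc = mean(abs(sub$logFC)),
                   n_genes = nrow(sub))
  })
  y <- per_line$mean_abs_logfc
  n <- length(y)
  if (stats::sd(y) == 0) {
    out <- list(per_line = per_line, rho = 0, p_value = 1,
                degenerate = TRUE)
    class(out) <- "feedback_trend"
    return(out)
  }
  rho_obs <- stats::cor(seq_len(n), y, method = "spearman")
  perms <- all_permutations(n)
  rhos <- apply(perms, 1, function(pm)
    stats::cor(seq_len(n), y[pm], method = "spearman"))
  p <- mean(rhos >= rho_obs - 1e-12)
  out <- list(per_line = per_line, rho = rho_obs, p_value = p,
              degenerate = FALSE)
  class(out) <- "feedback_trend"
  out
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' @export
print.feedback_trend <- function(x, ...) {
  cat(sprintf("<feedback_trend> Spearman rho = %.3f, permutation p = %.4g%s\n",
              x$rho, x$p_value,
              if (x$degenerate) " (degenerate: constant means)" else ""))
  print(x$per_line)
  invisible(x)
}

#' @export
tidy.feedback_trend <- function(x, ...) x$per_line

#' @export
glance.feedback_trend <- function(x, ...) {
  tibble::tibble(rho = x$rho, p_value = x$p_value,
                 degenerate = x$degenerate)
}
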