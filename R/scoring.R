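#' Per-gene maximal log fold change across lines
#'
#' For each gene, selects the log fold change of largest absolute value
#' across the assessed lines, sign retained, so that consistently
#' down-regulated genes keep their full magnitude for the two-tailed score.
#'
#' @param de A `de_table`.
#' @param lines Lines to consider (default: all lines present).
#' @return Tibble with columns `gene` and `x` (selected logFC).
#' @export
select_max_logfc <- function(de, lines = NULL) {
  if (!is.null(lines)) de <- dplyr::filter(de, .data$line %in% lines)
  de %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(x = .data$logFC[which.max(abs(.data$logFC))],
                     .groups = "drop") %>%
    dplyr::arrange(.data$gene)
}

#' Fit the empirical Gaussian null of the max-logFC distribution
#'
#' Most genes do not change expression, so the observed distribution of the
#' per-gene maximal logFC is dominated by the null.  Its mean and standard
#' deviation are estimated by Gaussian maximum likelihood (the sample mean,
#' and the standard deviation with the 1/n denominator).
#'
#' @param x Numeric vector of selected logFC values (length >= 30).
#' @return Object of class `null_model` with fields `mu`, `sigma`, `n`,
#'   `loglik`.
#' @examples
#' fit_null(rnorm(1000, 0.1, 0.4))
#' @export
fit_null <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 30) stop("need at least 30 values", call. = FALSE)
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma <= 0) stop("zero variance: cannot fit the null", call. = FALSE)
  ll <- sum(stats::dnorm(x, mu, sigma, log = TRUE))
  structure(list(mu = mu, sigma = sigma, n = length(x), loglik = ll),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("<null_model> Normal(mu = %.4g, sigma = %.4g), n = %d\n",
              x$mu, x$sigma, x$n))
  invisible(x)
}

#' @export
tidy.null_model <- function(x, ...) {
  tibble::tibble(term = c("mu", "sigma"),
                 estimate = c(x$mu, x$sigma))
}

#' @export
glance.null_model <- function(x, ...) {
  tibble::tibble(mu = x$mu, sigma = x$sigma, n = x$n, loglik = x$loglik)
}

#' Empirical-null gene score
#'
#' `score = |1 - 2 * Phi((x - mu) / sigma)|` where `Phi` is the standard
#' normal CDF: a two-tailed significance score in \[0, 1\] that is 0 at the
#' null mean and approaches 1 for extreme fold changes on either side.
#'
#' @param x Selected logFC value(s).
#' @param null A `null_model` from [fit_null()].
#' @return Numeric score(s) in \[0, 1\].
#' @examples
#' nm <- structure(list(mu = 0, sigma = 1), class = "null_model")
#' gene_score(c(0, 1.96, -1.96), nm)
#' @export
gene_score <- function(x, null) {
  abs(1 - 2 * stats::pnorm((x - null$mu) / null$sigma))
}

#' Edge weight from endpoint gene scores
#'
#' The relevance weight of an interaction is the product of the source and
#' target gene scores.
#'
#' @param source_score,target_score Scores in \[0, 1\].
#' @return Weight in \[0, 1\].
#' @export
edge_weight <- function(source_score, target_score) {
  stopifnot(all(source_score >= 0 & source_score <= 1),
            all(target_score >= 0 & target_score <= 1))
  source_score * target_score
}

#' Edge cost at a given penalty
#'
#' `cost = penalty * (1 - weight) + eps` with a fixed floor `eps = 1e-3`
#' that keeps every cost strictly positive (no zero-cost cycles in path
#' search).  Monotone decreasing in the weight, increasing in the penalty.
#'
#' @param weight Edge weight(s) in \[0, 1\].
#' @param penalty_c Penalty (> 0).
#' @param eps Positivity floor.
#' @return Cost(s) > 0.
#' @export
edge_cost <- function(weight, penalty_c, eps = 1e-3) {
  stopifnot(penalty_c > 0, all(weight >= 0 & weight <= 1))
  penalty_c * (1 - weight) + eps
}

#' Score the genes of a study and weight a network
#'
#' Convenience wrapper: selects the per-gene maximal logFC over the given
#' lines, fits the empirical null, scores every gene, and attaches product
#' weights to the network edges.  Network nodes absent from the expression
#' data receive score 0 (their edges are maximally expensive but still
#' traversable, so they can be recovered as connector genes).
#'
#' @param de A `de_table`.
#' @param network A `gene_network`.
#' @param lines Lines over which the maximal logFC is taken (default: all).
#' @return List with `scores` (tibble gene, x, score), `null` (the
#'   `null_model`) and `network` (edge tibble with a `weight` column).
#' @export
score_network <- function(de, network, lines = NULL) {
  sel <- select_max_logfc(de, lines)
  null <- fit_null(sel$x)
  sel$score <- gene_score(sel$x, null)
  lookup <- stats::setNames(sel$score, sel$gene)
  s_src <- unname(lookup[network$source])
  s_tgt <- unname(lookup[network$target])
  s_src[is.na(s_src)] <- 0
  s_tgt[is.na(s_tgt)] <- 0
  network$weight <- edge_weight(s_src, s_tgt)
  list(scores = sel, null = null, network = network)
}
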