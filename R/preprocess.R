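#' Quantile normalization
#'
#' Forces every sample onto the same distribution: after normalization each
#' sample's sorted values equal the across-sample mean of order statistics.
#' Ties within a sample receive the mean of the quantile values they span.
#'
#' @param x An [expression_set()] or a numeric matrix (genes x samples).
#' @return Object of the same class as `x`, normalized.
#' @examples
#' m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
#' rownames(m) <- paste0("g", 1:3)
#' quantile_normalize(m)
#' @export
quantile_normalize <- function(x) {
  if (inherits(x, "expression_set")) {
    x$values <- quantile_normalize(x$values)
    return(x)
  }
  m <- as.matrix(x)
  if (ncol(m) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(is.na(m))) stop("missing values not allowed", call. = FALSE)
  ref <- rowMeans(apply(m, 2, sort))
  cum <- c(0, cumsum(ref))
  out <- apply(m, 2, function(col) {
    lo <- rank(col, ties.method = "min")
    hi <- rank(col, ties.method = "max")
    (cum[hi + 1] - cum[lo]) / (hi - lo + 1)
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Collapse probes to genes
#'
#' Probes mapping to more than one gene (non-unique probes) are removed
#' entirely; each remaining gene's value per sample is the arithmetic mean
#' over its probes.  Genes with no remaining probe are absent from the
#' output.
#'
#' @param es An [expression_set()] whose rows are probes.
#' @param probe_to_gene Data frame with columns `probe` and `gene`; a probe
#'   may map to 0, 1 or more genes.
#' @return An [expression_set()] whose rows are genes.
#' @export
collapse_probes <- function(es, probe_to_gene) {
  map <- tibble::as_tibble(probe_to_gene)[, c("probe", "gene")]
  map <- dplyr::distinct(map)
  multi <- map %>%
    dplyr::count(.data$probe) %>%
    dplyr::filter(.data$n > 1) %>%
    dplyr::pull("probe")
  map <- dplyr::filter(map, !(.data$probe %in% multi),
                       .data$probe %in% rownames(es$values))
  if (nrow(map) == 0) stop("no uniquely mapping probe found", call. = FALSE)
  sub <- es$values[map$probe, , drop = FALSE]
  agg <- rowsum(sub, group = map$gene)
  counts <- as.vector(table(map$gene)[rownames(agg)])
  out <- agg / counts
  expression_set(out[sort(rownames(out)), , drop = FALSE], es$samples)
}

#' Moderated two-group differential expression for one line
#'
#' Compares one line against the reference line with an empirical-Bayes
#' moderated t-statistic.  Per gene the log fold change is the difference of
#' line means (log2 scale).  The pooled within-group variance of every gene
#' is shrunk towards a common prior: the prior degrees of freedom `d0` and
#' prior variance `s0^2` are estimated from the ensemble of gene variances
#' by the method of moments on `log s^2` (scaled-F model), and the posterior
#' variance is `(d0 s0^2 + d s^2) / (d0 + d)`.  The moderated t has
#' `d0 + d` degrees of freedom.
#'
#' @param es An [expression_set()].
#' @param line Line to test.
#' @param reference_line Reference line.
#' @param d0_override If not `NULL`, forces the prior degrees of freedom
#'   (0 recovers the ordinary pooled two-sample t).
#' @return Tibble with columns `gene`, `line`, `logFC`, `t`, `p`.
#' @export
moderated_de <- function(es, line, reference_line, d0_override = NULL) {
  sm <- es$samples
  i1 <- which(sm$line == line)
  i0 <- which(sm$line == reference_line)
  if (length(i1) < 2 || length(i0) < 2) {
    stop("need at least 2 replicates per line (", line, " vs ",
         reference_line, ")", call. = FALSE)
  }
  x1 <- es$values[, i1, drop = FALSE]
  x0 <- es$values[, i0, drop = FALSE]
  n1 <- length(i1); n0 <- length(i0)
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  logfc <- m1 - m0
  ss <- rowSums((x1 - m1)^2) + rowSums((x0 - m0)^2)
  d <- n1 + n0 - 2
  s2 <- ss / d
  if (is.null(d0_override)) {
    pr <- fit_variance_prior(s2, d)
  } else {
    d0 <- as.numeric(d0_override)
    pr <- list(d0 = d0,
               s0_sq = if (d0 > 0) mean(s2) else NA_real_)
  }
  if (pr$d0 == 0) {
    s2_post <- s2
  } else if (is.infinite(pr$d0)) {
    s2_post <- rep(pr$s0_sq, length(s2))
  } else {
    s2_post <- (pr$d0 * pr$s0_sq + d * s2) / (pr$d0 + d)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n0))
  tstat <- ifelse(se > 0, logfc / se, ifelse(logfc == 0, 0, sign(logfc) * Inf))
  df_total <- pr$d0 + d
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- tibble::tibble(gene = rownames(es$values), line = line,
                        logFC = unname(logfc), t = unname(tstat),
                        p = unname(p))
  attr(out, "prior") <- list(d0 = pr$d0, s0_sq = pr$s0_sq, d = d)
  out
}

# Method-of-moments fit of the scaled-F variance prior on z = log s^2:
# s^2 ~ s0^2 * F(d, d0), so var(z) = trigamma(d/2) + trigamma(d0/2) and
# mean(z) = log s0^2 + digamma(d/2) - log(d/2) - digamma(d0/2) + log(d0/2).
fit_variance_prior <- function(s2, d) {
  z <- log(pmax(s2, 1e-300))
  ok <- s2 > 0
  if (sum(ok) < 2) stop("not enough positive gene variances", call. = FALSE)
  zv <- stats::var(z[ok])
  excess <- zv - trigamma(d / 2)
  if (excess <= 1e-8) {
    d0 <- Inf
    s0_sq <- exp(mean(z[ok]) - digamma(d / 2) + log(d / 2))
  } else {
    half_d0 <- trigamma_inverse(excess)
    d0 <- 2 * half_d0
    s0_sq <- exp(mean(z[ok]) - digamma(d / 2) + log(d / 2) +
                   digamma(half_d0) - log(half_d0))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton inversion of trigamma (y > 0).
trigamma_inverse <- function(y) {
  if (y <= 0) stop("trigamma_inverse needs y > 0", call. = FALSE)
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    delta <- (trigamma(x) - y) / psigamma(x, deriv = 2)
    x_new <- x - delta
    if (x_new <= 0) x_new <- x / 2
    if (abs(x_new - x) < 1e-10 * x) {
      x <- x_new
      break
    }
    x <- x_new
  }
  x
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Apply fold-change and FDR thresholds
#'
#' Flags a gene as differentially expressed when its adjusted p-value is at
#' most `fdr_threshold` and `|logFC| >= log2(fc_threshold)` (the linear
#' fold-change bound interpreted on the log2 scale, two-sided).
#'
#' @param de A DE tibble with columns `logFC` and `adj_p`.
#' @param fc_threshold Linear fold-change bound (> 1).
#' @param fdr_threshold Adjusted-p bound.
#' @return `de` with a logical `de_flag` column (replaced if present).
#' @export
apply_thresholds <- function(de, fc_threshold = 1.5, fdr_threshold = 0.05) {
  stopifnot(fc_threshold > 1)
  de$de_flag <- de$adj_p <= fdr_threshold &
    abs(de$logFC) >= log2(fc_threshold)
  de
}

#' Full differential-expression stage
#'
#' Runs [moderated_de()] for every non-reference line (or the given lines),
#' adjusts p-values per line with [bh_adjust()] and applies the thresholds.
#'
#' @param es An [expression_set()].
#' @param reference_line Reference line identifier.
#' @param lines Lines to test (default: all non-reference lines, in column
#'   order).
#' @param fc_threshold,fdr_threshold Thresholds, see [apply_thresholds()].
#' @return A `de_table` tibble: one row per gene x line with columns `gene`,
#'   `line`, `logFC`, `t`, `p`, `adj_p`, `de_flag`.
#' @export
de_test <- function(es, reference_line, lines = NULL,
                    fc_threshold = 1.5, fdr_threshold = 0.05) {
  if (is.null(lines)) {
    lines <- setdiff(expr_lines(es), reference_line)
  }
  out <- purrr::map_dfr(lines, function(ln) {
    tab <- moderated_de(es, ln, reference_line)
    tab$adj_p <- bh_adjust(tab$p)
    tab
  })
  out <- apply_thresholds(out, fc_threshold, fdr_threshold)
  class(out) <- c("de_table", class(tibble::tibble()))
  attr(out, "reference_line") <- reference_line
  out
}

#' PCA quality control of replicate consistency
#'
#' Gene-centered principal component analysis of the samples.  The summary
#' compares the dispersion of replicate samples around their line centroid
#' (within-line) with the dispersion of the line centroids (between-line):
#' consistent replicates give a within/between ratio well below 1.
#'
#' @param es An [expression_set()] with at least 3 samples.
#' @param n_components Number of components to return (default 2).
#' @return Object of class `pca_qc`: list with `scores` (tibble: sample,
#'   line, replicate, PC1, PC2, ...), `var_explained`, and `dispersion`
#'   (within, between, ratio).
#' @export
pca_qc <- function(es, n_components = 2L) {
  if (ncol(es$values) < 3) stop("need at least 3 samples", call. = FALSE)
  centered <- es$values - rowMeans(es$values)
  pc <- stats::prcomp(t(centered), center = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE])
  scores <- dplyr::bind_cols(es$samples, scores)
  centroids <- scores %>%
    dplyr::group_by(.data$line) %>%
    dplyr::summarise(dplyr::across(dplyr::starts_with("PC"), mean),
                     .groups = "drop")
  cm <- as.matrix(centroids[, -1])
  sm <- as.matrix(scores[, -(1:3)])
  within <- mean(sqrt(rowSums(
    (sm - cm[match(scores$line, centroids$line), , drop = FALSE])^2)))
  grand <- colMeans(cm)
  between <- mean(sqrt(rowSums(sweep(cm, 2, grand)^2)))
  var_expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores,
                 var_explained = var_expl[seq_len(k)],
                 dispersion = c(within = within, between = between,
                                ratio = within / max(between, 1e-300))),
            class = "pca_qc")
}

#' @export
print.pca_qc <- function(x, ...) {
  cat(sprintf(
    "<pca_qc> %d samples; PC1 %.1f%%, PC2 %.1f%%; within/between = %.3g\n",
    nrow(x$scores), 100 * x$var_explained[1],
    100 * ifelse(length(x$var_explained) > 1, x$var_explained[2], NA),
    x$dispersion[["ratio"]]))
  invisible(x)
}

#' @export
tidy.pca_qc <- function(x, ...) x$scores

#' @export
glance.pca_qc <- function(x, ...) {
  tibble::tibble(within = x$dispersion[["within"]],
                 between = x$dispersion[["between"]],
                 ratio = x$dispersion[["ratio"]],
                 pc1_var = x$var_explained[1])
}
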