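#' Run the full analysis pipeline
#'
#' Chains the stages on prepared inputs: differential expression of every
#' non-reference line against the reference, group classification, optional
#' marker concordance, empirical-null gene scoring and edge weighting, and
#' subnetwork inference with the penalty sweep.  Seed genes for the network
#' stage are the union of groups A, B and C (restored, compensatory and
#' non-restored genes), as in the emulated study design.
#'
#' @param es An [expression_set()] (already normalized / probe-collapsed).
#' @param network A `gene_network`.
#' @param cfg A [pipeline_config()].
#' @param markers Optional marker tibble (see [read_markers()]).
#' @param seeds Optional explicit seed genes; default: union of groups
#'   A, B, C.
#' @return List of class `suppnet_result` with elements `de`, `groups`,
#'   `group_sizes`, `markers` (or `NULL`), `scores`, `null`,
#'   `subnetworks`, `config`.
#' @export
run_pipeline <- function(es, network, cfg = pipeline_config(),
                         markers = NULL, seeds = NULL) {
  validate_config(cfg)
  test_lines <- c(cfg$mutant_line, cfg$suppressor_lines)
  de <- de_test(es, cfg$reference_line, lines = test_lines,
                fc_threshold = cfg$fc_threshold,
                fdr_threshold = cfg$fdr_threshold)
  groups <- classify_groups(de, cfg$mutant_line, cfg$suppressor_lines)
  marker_res <- if (!is.null(markers)) {
    marker_concordance(de, markers, cfg$mutant_line, cfg$suppressor_lines)
  }
  scored <- score_network(de, network, lines = test_lines)
  if (is.null(seeds)) {
    seeds <- groups$gene[groups$label %in% c("A", "B", "C")]
  }
  subnets <- infer_subnetworks(scored$network, seeds, cfg,
                               scores = scored$scores, groups = groups)
  structure(list(de = de, groups = groups,
                 group_sizes = group_sizes(groups),
                 markers = marker_res,
                 scores = scored$scores, null = scored$null,
                 subnetworks = subnets, config = cfg),
            class = "suppnet_result")
}

#' @export
print.suppnet_result <- function(x, ...) {
  cat("<suppnet_result>\n")
  n_de <- length(unique(x$de$gene[x$de$de_flag]))
  cat(sprintf("  DE: %d unique genes across %d contrasts\n", n_de,
              length(unique(x$de$line))))
  gs <- x$group_sizes
  cat("  groups:",
      paste(sprintf("%s=%d(%d)", gs$label, gs$n, gs$n_core),
            collapse = " "), "\n")
  cat(sprintf("  null: mu = %.4g, sigma = %.4g\n", x$null$mu,
              x$null$sigma))
  print(x$subnetworks)
  invisible(x)
}

#' @export
glance.suppnet_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      n_de_genes = length(unique(x$de$gene[x$de$de_flag])),
      null_mu = x$null$mu, null_sigma = x$null$sigma),
    glance(x$subnetworks))
}
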