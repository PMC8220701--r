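#' Pipeline configuration
#'
#' Bundles every tunable parameter of the comparative-transcriptome /
#' subnetwork-inference pipeline into a validated list.  Defaults mirror the
#' study design the pipeline emulates: one wild-type reference, one mutant,
#' three activation-tag suppressor lines, a linear fold-change bound of 1.5
#' together with a Benjamini-Hochberg FDR bound of 0.05 for differential
#' expression, and a log-spaced edge-penalty sweep (28 penalties between 0.1
#' and 5) with bounded path search (at most 4 edges per path, 50 best paths
#' per seed pair), a Jaccard stability bound of 0.5 and a subnetwork size
#' bound of 500 edges.
#'
#' @param reference_line Identifier of the wild-type reference line.
#' @param mutant_line Identifier of the primary mutant line.
#' @param suppressor_lines Character vector of suppressor line identifiers,
#'   ordered; position 1/2/3 defines the line-specific group labels D/E/F.
#' @param fc_threshold Linear fold-change bound (> 1); applied as
#'   `|logFC| >= log2(fc_threshold)`.
#' @param fdr_threshold Adjusted-p bound in (0, 1].
#' @param cost_min,cost_max Bounds of the edge-penalty sweep (both > 0,
#'   `cost_min < cost_max`).
#' @param cost_steps Number of log-spaced penalties in the sweep (>= 2,
#'   endpoints included).
#' @param path_length Maximum number of edges per path (>= 1).
#' @param k_paths Number of best paths retained per ordered seed pair (>= 1).
#' @param jaccard_min Stability bound in \[0, 1\]; penalties whose subnetwork
#'   has mean pairwise Jaccard below it are rejected.
#' @param max_edges Subnetwork size bound (unique undirected edges).
#' @param resamples,fraction Stability-selection ensemble: number of seed
#'   subsamples and the fraction of seeds kept in each.
#' @param rng_seed Integer seed used by all stochastic steps.
#'
#' @return A list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config()
#' cfg$fc_threshold
#' @export
pipeline_config <- function(reference_line = "WS2",
                            mutant_line = "bri1-5",
                            suppressor_lines = c("bri1-5/brs1-1D",
                                                 "bri1-5/bri1-1D",
                                                 "bri1-5/bak1-1D"),
                            fc_threshold = 1.5,
                            fdr_threshold = 0.05,
                            cost_min = 0.1,
                            cost_max = 5,
                            cost_steps = 28L,
                            path_length = 4L,
                            k_paths = 50L,
                            jaccard_min = 0.5,
                            max_edges = 500L,
                            resamples = 10L,
                            fraction = 0.8,
                            rng_seed = 1L) {
  cfg <- list(
    reference_line = as.character(reference_line),
    mutant_line = as.character(mutant_line),
    suppressor_lines = as.character(suppressor_lines),
    fc_threshold = as.numeric(fc_threshold),
    fdr_threshold = as.numeric(fdr_threshold),
    cost_min = as.numeric(cost_min),
    cost_max = as.numeric(cost_max),
    cost_steps = as.integer(cost_steps),
    path_length = as.integer(path_length),
    k_paths = as.integer(k_paths),
    jaccard_min = as.numeric(jaccard_min),
    max_edges = as.integer(max_edges),
    resamples = as.integer(resamples),
    fraction = as.numeric(fraction),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (cfg$fc_threshold <= 1) {
    stop("`fc_threshold` must be > 1 (linear fold change)", call. = FALSE)
  }
  if (cfg$fdr_threshold <= 0 || cfg$fdr_threshold > 1) {
    stop("`fdr_threshold` must be in (0, 1]", call. = FALSE)
  }
  if (cfg$cost_min <= 0) stop("`cost_min` must be > 0", call. = FALSE)
  if (cfg$cost_min >= cfg$cost_max) {
    stop("`cost_min` must be smaller than `cost_max`", call. = FALSE)
  }
  if (cfg$cost_steps < 2L) stop("`cost_steps` must be >= 2", call. = FALSE)
  if (cfg$path_length < 1L) stop("`path_length` must be >= 1", call. = FALSE)
  if (cfg$k_paths < 1L) stop("`k_paths` must be >= 1", call. = FALSE)
  if (cfg$jaccard_min < 0 || cfg$jaccard_min > 1) {
    stop("`jaccard_min` must be in [0, 1]", call. = FALSE)
  }
  if (cfg$fraction <= 0 || cfg$fraction > 1) {
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  }
  if (cfg$resamples < 2L) stop("`resamples` must be >= 2", call. = FALSE)
  invisible(cfg)
}

#' Penalty grid of the edge-cost sweep
#'
#' Inclusive log-spaced grid between `cost_min` and `cost_max`: the ratio of
#' consecutive penalties is constant.
#'
#' @param cfg A [pipeline_config()].
#' @return Numeric vector of length `cost_steps`.
#' @export
penalty_grid <- function(cfg) {
  exp(seq(log(cfg$cost_min), log(cfg$cost_max), length.out = cfg$cost_steps))
}

#' Read / write a pipeline configuration
#'
#' Flat YAML with one key per [pipeline_config()] field.  Keys absent from the
#' file keep their defaults; unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return `read_config()` returns a `pipeline_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param cfg A `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat("  reference:", x$reference_line, " mutant:", x$mutant_line, "\n")
  cat("  suppressors:", paste(x$suppressor_lines, collapse = ", "), "\n")
  cat(sprintf("  DE: |FC| >= %.3g, FDR <= %.3g\n",
              x$fc_threshold, x$fdr_threshold))
  cat(sprintf(
    "  sweep: %d penalties in [%.3g, %.3g]; paths <= %d edges, k = %d\n",
    x$cost_steps, x$cost_min, x$cost_max, x$path_length, x$k_paths))
  cat(sprintf("  filters: Jaccard >= %.2g, edges <= %d; seed %d\n",
              x$jaccard_min, x$max_edges, x$rng_seed))
  invisible(x)
}
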