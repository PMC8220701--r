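#' Expression set container
#'
#' A light container for a gene-by-sample matrix of log2 intensities plus a
#' sample sheet mapping each sample to a line (genotype) and replicate.
#'
#' @param values Numeric matrix, rows = genes/probes (rownames required),
#'   columns = samples (colnames required).
#' @param samples Data frame with columns `sample`, `line`, `replicate`;
#'   every column of `values` must appear exactly once in `samples$sample`.
#'
#' @return An object of class `expression_set`: a list with elements
#'   `values` (matrix) and `samples` (tibble, ordered as the matrix columns).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' meta <- data.frame(sample = paste0("s", 1:4),
#'                    line = rep(c("WT", "mut"), each = 2),
#'                    replicate = rep(1:2, 2))
#' es <- expression_set(m, meta)
#' dim(es)
#' @export
expression_set <- function(values, samples) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` needs gene rownames and sample colnames", call. = FALSE)
  }
  storage.mode(values) <- "double"
  samples <- tibble::as_tibble(samples)
  req <- c("sample", "line", "replicate")
  if (!all(req %in% names(samples))) {
    stop("`samples` must have columns sample, line, replicate", call. = FALSE)
  }
  missing <- setdiff(colnames(values), samples$sample)
  if (length(missing) > 0) {
    stop("sample(s) absent from metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(samples$sample)) {
    stop("duplicated sample identifiers in metadata", call. = FALSE)
  }
  samples <- samples[match(colnames(values), samples$sample), req]
  samples$sample <- as.character(samples$sample)
  samples$line <- as.character(samples$line)
  structure(list(values = values, samples = samples),
            class = "expression_set")
}

#' @export
dim.expression_set <- function(x) dim(x$values)

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("<expression_set> %d genes x %d samples (%d lines)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$samples$line))))
  invisible(x)
}

#' Lines present in an expression set
#' @param es An [expression_set()].
#' @return Character vector of line identifiers, in column order.
#' @export
expr_lines <- function(es) unique(es$samples$line)

#' Long (tidy) view of an expression set
#'
#' @param x An [expression_set()].
#' @param ... Unused.
#' @return A tibble with columns `gene`, `sample`, `line`, `replicate`,
#'   `value`.
#' @export
tidy.expression_set <- function(x, ...) {
  long <- tibble::tibble(
    gene = rep(rownames(x$values), times = ncol(x$values)),
    sample = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
  dplyr::left_join(long, x$samples, by = "sample")[
    , c("gene", "sample", "line", "replicate", "value")]
}

#' @export
glance.expression_set <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$values),
                 n_samples = ncol(x$values),
                 n_lines = length(unique(x$samples$line)))
}
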