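#' Classify genes into restored / compensatory / non-restored groups
#'
#' Applies the suppressor-line set logic to per-line differential-expression
#' flags (each line called against the common wild-type reference):
#'
#' * **A** (restored): DE in the mutant and *not* DE in at least two of the
#'   three suppressors; core = not DE in all three.
#' * **B** (compensatory): not DE in the mutant, DE in at least two
#'   suppressors; core = DE in all three.
#' * **C** (non-restored): DE in the mutant and in at least two suppressors;
#'   core = DE in all three.
#' * **D/E/F** (line-specific): not DE in the mutant and DE in exactly one
#'   suppressor; D, E and F track the identity of the first, second and
#'   third entry of `suppressor_lines` respectively.
#' * **none**: everything else.
#'
#' Membership is purely flag-based: sign or magnitude of the fold change
#' plays no role, and a gene DE in the mutant with exactly one DE suppressor
#' still belongs to A (two suppressors are not DE).
#'
#' @param de A `de_table` (from [de_test()]) or any tibble with columns
#'   `gene`, `line`, `de_flag` covering the mutant and all three suppressors.
#' @param mutant_line Mutant line identifier.
#' @param suppressor_lines Exactly three suppressor line identifiers,
#'   ordered (defines D/E/F).
#' @return Tibble with columns `gene`, `label` (factor with levels A-F,
#'   none) and `core` (logical).
#' @examples
#' flags <- tibble::tibble(
#'   gene = rep(c("g1", "g2"), each = 4),
#'   line = rep(c("mut", "s1", "s2", "s3"), 2),
#'   de_flag = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
#' )
#' classify_groups(flags, "mut", c("s1", "s2", "s3"))
#' @export
classify_groups <- function(de, mutant_line, suppressor_lines) {
  if (length(suppressor_lines) != 3) {
    stop("exactly three suppressor lines are required", call. = FALSE)
  }
  need <- c(mutant_line, suppressor_lines)
  missing <- setdiff(need, unique(de$line))
  if (length(missing) > 0) {
    stop("line(s) absent from DE flags: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  wide <- de %>%
    dplyr::filter(.data$line %in% need) %>%
    dplyr::select("gene", "line", "de_flag") %>%
    tidyr::pivot_wider(names_from = "line", values_from = "de_flag")
  if (any(is.na(wide[need]))) {
    stop("every gene needs a DE flag for the mutant and all suppressors",
         call. = FALSE)
  }
  m <- wide[[mutant_line]]
  s <- as.matrix(wide[suppressor_lines])
  n_de <- rowSums(s)
  label <- rep("none", nrow(wide))
  core <- rep(FALSE, nrow(wide))

  a <- m & (3 - n_de) >= 2
  b <- !m & n_de >= 2
  cc <- m & n_de >= 2
  label[a] <- "A"; core[a] <- n_de[a] == 0
  label[b] <- "B"; core[b] <- n_de[b] == 3
  label[cc] <- "C"; core[cc] <- n_de[cc] == 3
  single <- !m & n_de == 1
  for (i in 1:3) {
    hit <- single & s[, i]
    label[hit] <- c("D", "E", "F")[i]
  }
  tibble::tibble(
    gene = wide$gene,
    label = factor(label, levels = c("A", "B", "C", "D", "E", "F", "none")),
    core = core
  )
}

#' Group size summary
#'
#' @param groups Output of [classify_groups()].
#' @return Tibble with columns `label`, `n`, `n_core`.
#' @export
group_sizes <- function(groups) {
  groups %>%
    dplyr::group_by(.data$label, .drop = FALSE) %>%
    dplyr::summarise(n = dplyr::n(), n_core = sum(.data$core),
                     .groups = "drop")
}

#' Marker-gene concordance with literature direction
#'
#' Retains the markers that are differentially expressed in the mutant line
#' (the study-relevant subset), reports per marker and line whether the gene
#' is up-regulated, down-regulated or not DE relative to the reference, and
#' counts per suppressor how many retained markers are *restored* (not DE in
#' that suppressor).  Markers absent from the DE table are reported via a
#' message and skipped.
#'
#' @param de A `de_table` covering mutant and suppressor lines.
#' @param markers Marker tibble from [read_markers()] (columns `gene`,
#'   `direction`, `n_refs`).
#' @param mutant_line,suppressor_lines Line identifiers.
#' @return Object of class `marker_concordance`: list with `table` (one row
#'   per retained marker: literature direction, observed status per line,
#'   and whether the mutant call matches the literature direction) and
#'   `restored` (per suppressor: number of retained markers restored).
#' @export
marker_concordance <- function(de, markers, mutant_line, suppressor_lines) {
  present <- markers$gene %in% unique(de$gene)
  if (any(!present)) {
    message("skipping ", sum(!present),
            " marker(s) absent from the expression data: ",
            paste(utils::head(markers$gene[!present], 5), collapse = ", "),
            if (sum(!present) > 5) ", ..." else "")
  }
  markers <- markers[present, , drop = FALSE]
  lines <- c(mutant_line, suppressor_lines)
  status <- de %>%
    dplyr::filter(.data$gene %in% markers$gene, .data$line %in% lines) %>%
    dplyr::mutate(status = dplyr::case_when(
      !.data$de_flag ~ "not_de",
      .data$logFC > 0 ~ "up",
      TRUE ~ "down"
    )) %>%
    dplyr::select("gene", "line", "status") %>%
    tidyr::pivot_wider(names_from = "line", values_from = "status")
  tab <- dplyr::inner_join(markers, status, by = "gene") %>%
    dplyr::filter(.data[[mutant_line]] != "not_de") %>%
    dplyr::mutate(
      mutant_agrees = .data[[mutant_line]] == .data$direction)
  restored <- tibble::tibble(
    line = suppressor_lines,
    n_restored = vapply(suppressor_lines,
                        function(l) sum(tab[[l]] == "not_de"), integer(1),
                        USE.NAMES = FALSE),
    n_markers = nrow(tab)
  )
  structure(list(table = tab, restored = restored,
                 n_candidates = nrow(markers)),
            class = "marker_concordance")
}

#' @export
print.marker_concordance <- function(x, ...) {
  cat(sprintf("<marker_concordance> %d candidate markers, %d DE in mutant\n",
              x$n_candidates, nrow(x$table)))
  print(x$restored)
  invisible(x)
}

#' @export
tidy.marker_concordance <- function(x, ...) x$table

#' @export
glance.marker_concordance <- function(x, ...) {
  tibble::tibble(n_candidates = x$n_candidates,
                 n_retained = nrow(x$table),
                 best_suppressor =
                   x$restored$line[which.max(x$restored$n_restored)])
}

#' Squared correlation of relative differential expression
#'
#' Correlates, over all genes, the expression change of two lines measured
#' relative to a common base line (typically the mutant): per gene the
#' relative logFC of line x is `logFC(x) - logFC(base)` (both against the
#' wild-type reference, so the difference is the x-vs-base change).  Returns
#' the squared Pearson correlation, which is sign-blind by construction.
#'
#' @param de A `de_table` containing `base_line`, `line_x` and `line_y`.
#' @param base_line Common base line for the relative change.
#' @param line_x,line_y Lines to compare.
#' @return The squared Pearson correlation (scalar).
#' @export
relative_de_correlation <- function(de, base_line, line_x, line_y) {
  wide <- de %>%
    dplyr::filter(.data$line %in% c(base_line, line_x, line_y)) %>%
    dplyr::select("gene", "line", "logFC") %>%
    tidyr::pivot_wider(names_from = "line", values_from = "logFC") %>%
    tidyr::drop_na()
  if (nrow(wide) < 3) stop("need at least 3 genes", call. = FALSE)
  rx <- wide[[line_x]] - wide[[base_line]]
  ry <- wide[[line_y]] - wide[[base_line]]
  if (identical(line_x, line_y)) return(1)
  stats::cor(rx, ry)^2
}
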