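#' Read an expression matrix with its sample sheet
#'
#' The matrix is a TSV whose header row holds sample identifiers and whose
#' first column holds gene (or probe) identifiers; values are log2
#' intensities.  The metadata TSV maps each sample to a line and replicate
#' (columns `sample`, `line`, `replicate`).  Gene identifiers are opaque,
#' case-sensitive strings; duplicates are allowed only upstream of probe
#' collapsing.
#'
#' @param path Path to the expression TSV.
#' @param metadata Path to the metadata TSV.
#' @return An [expression_set()].
#' @export
read_expression <- function(path, metadata) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta <- readr::read_tsv(metadata, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- ids
  if (any(is.na(m))) stop("expression matrix contains missing values",
                          call. = FALSE)
  expression_set(m, meta)
}

#' @rdname read_expression
#' @param es An [expression_set()] to write.
#' @export
write_expression <- function(es, path, metadata) {
  tab <- tibble::as_tibble(es$values, rownames = "gene")
  readr::write_tsv(tab, path, progress = FALSE)
  readr::write_tsv(es$samples, metadata, progress = FALSE)
  invisible(path)
}

#' Interaction edge types
#' @keywords internal
EDGE_TYPES <- c("regulatory", "ppi", "metabolic")

new_gene_network <- function(edges) {
  edges <- tibble::as_tibble(edges)[, c("source", "target", "type")]
  class(edges) <- c("gene_network", class(tibble::tibble()))
  edges
}

#' Read a typed interaction edge list
#'
#' TSV with columns `source`, `target`, `type` where the type is one of
#' `regulatory`, `ppi`, `metabolic`.  Regulatory and metabolic edges are
#' directed source to target; protein-protein (`ppi`) edges are undirected
#' and stored with their endpoints in lexicographic order.  Duplicate
#' `(source, target, type)` rows are collapsed and self-loops dropped.
#' Row order of the input does not affect the result.
#'
#' @param path Path to the edge-list TSV.
#' @return A `gene_network` tibble with columns `source`, `target`, `type`.
#' @export
read_network <- function(path) {
  edges <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  if (!all(c("source", "target", "type") %in% names(edges))) {
    stop("edge list needs columns source, target, type", call. = FALSE)
  }
  as_gene_network(edges)
}

#' Coerce an edge table to a `gene_network`
#'
#' Applies the same canonicalization as [read_network()]: unknown types are
#' an error, ppi endpoints are sorted, duplicates and self-loops removed,
#' rows ordered deterministically.
#'
#' @param edges Data frame with columns `source`, `target`, `type`.
#' @return A `gene_network` tibble.
#' @export
as_gene_network <- function(edges) {
  edges <- tibble::as_tibble(edges)
  bad <- setdiff(unique(edges$type), EDGE_TYPES)
  if (length(bad) > 0) {
    stop("unknown edge type(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(EDGE_TYPES, collapse = ", "), call. = FALSE)
  }
  edges <- edges %>%
    dplyr::mutate(source = as.character(.data$source),
                  target = as.character(.data$target)) %>%
    dplyr::filter(.data$source != .data$target) %>%
    dplyr::mutate(
      s = ifelse(.data$type == "ppi",
                 pmin(.data$source, .data$target), .data$source),
      t = ifelse(.data$type == "ppi",
                 pmax(.data$source, .data$target), .data$target)
    ) %>%
    dplyr::distinct(.data$s, .data$t, .data$type) %>%
    dplyr::rename(source = "s", target = "t") %>%
    dplyr::arrange(.data$source, .data$target, .data$type)
  new_gene_network(edges)
}

#' @rdname read_network
#' @param network A `gene_network`.
#' @export
write_network <- function(network, path) {
  readr::write_tsv(network[, c("source", "target", "type")], path,
                   progress = FALSE)
  invisible(path)
}

#' Nodes of a network
#' @param network A `gene_network` (or any edge tibble).
#' @return Sorted character vector of node identifiers.
#' @export
network_nodes <- function(network) {
  sort(unique(c(network$source, network$target)))
}

#' Read / write gene-set collections (GMT)
#'
#' GMT dialect: one set per line, `name<TAB>description<TAB>member...`.
#' Members are deduplicated; duplicate set names are an error.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names_)) {
    stop("duplicate gene-set name(s): ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- names_
  sets
}

#' @rdname read_gene_sets
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a marker-gene table
#'
#' TSV with columns `gene`, `direction` (`up` or `down`: literature response
#' to exogenous hormone treatment or a gain-of-function signaling mutation)
#' and `n_refs` (number of independent supporting references).  Markers with
#' fewer than `min_refs` references are dropped.
#'
#' @param path Path to the marker TSV.
#' @param min_refs Minimum number of supporting references (default 5).
#' @return A tibble with columns `gene`, `direction`, `n_refs`.
#' @export
read_markers <- function(path, min_refs = 5L) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene", "direction", "n_refs") %in% names(tab))) {
    stop("marker table needs columns gene, direction, n_refs", call. = FALSE)
  }
  bad <- setdiff(unique(tab$direction), c("up", "down"))
  if (length(bad) > 0) {
    stop("marker direction must be 'up' or 'down'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dplyr::filter(tab, .data$n_refs >= min_refs)
}

#' Read a flat gene-to-term annotation table
#'
#' Two-column TSV `gene<TAB>term` (no header needed; a `gene\tterm` header
#' row is tolerated).  Terms are returned as a named list of gene sets, the
#' shape expected by [hypergeom_enrich()].  No propagation up any ontology
#' graph is performed: annotations are used as given.
#'
#' @param path Path to the annotation TSV.
#' @return Named list mapping term to a character vector of genes.
#' @export
read_annotations <- function(path) {
  tab <- readr::read_tsv(path, col_names = c("gene", "term"),
                         show_col_types = FALSE, progress = FALSE,
                         col_types = "cc")
  if (nrow(tab) > 0 && tab$gene[1] == "gene" && tab$term[1] == "term") {
    tab <- tab[-1, ]
  }
  lapply(split(tab$gene, tab$term), unique)
}

#' Write final subnetworks to node/edge tables and GraphML
#'
#' Emits `<prefix>_nodes.tsv` (gene, component, group label, core flag,
#' connector flag, gene score), `<prefix>_edges.tsv` (source, target, type,
#' weight, component) and `<prefix>.graphml` carrying the same attributes.
#' An empty subnetwork list produces valid empty-bodied files.
#'
#' @param subnetworks A `subnetwork_set` from [infer_subnetworks()].
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths.
#' @export
write_subnetworks <- function(subnetworks, prefix) {
  nodes <- tidy(subnetworks)
  edges <- subnetworks$edges
  node_path <- paste0(prefix, "_nodes.tsv")
  edge_path <- paste0(prefix, "_edges.tsv")
  gml_path <- paste0(prefix, ".graphml")
  readr::write_tsv(nodes, node_path, progress = FALSE)
  readr::write_tsv(edges, edge_path, progress = FALSE)
  g <- igraph::make_empty_graph(directed = FALSE)
  if (nrow(nodes) > 0) {
    g <- igraph::graph_from_data_frame(
      edges[, c("source", "target", "type", "weight", "component")],
      directed = FALSE,
      vertices = nodes
    )
  }
  igraph::write_graph(g, gml_path, format = "graphml")
  invisible(c(nodes = node_path, edges = edge_path, graphml = gml_path))
}
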