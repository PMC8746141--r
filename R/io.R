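#' Read and write connectome files
#'
#' The CSV edge-list format has header `i,j,n,l`, with integer node id
#' columns referencing an optional companion node table with header
#' `id,label`. GraphML files are read via igraph and must carry numeric
#' edge attributes `n` (fiber count) and `l` (fiber length).
#'
#' @param path Edge-list CSV path.
#' @param nodes_path Optional node-table CSV path.
#' @return A [connectome()].
#' @export
read_connectome <- function(path, nodes_path = NULL) {
  edges <- readr::read_csv(path, show_col_types = FALSE)
  nodes <- if (!is.null(nodes_path)) {
    readr::read_csv(nodes_path, show_col_types = FALSE)
  } else {
    NULL
  }
  connectome(edges, nodes)
}

#' @rdname read_connectome
#' @param x A [connectome()].
#' @return `write_connectome()` returns `path` invisibly.
#' @export
write_connectome <- function(x, path, nodes_path = NULL) {
  x <- as_connectome(x)
  readr::write_csv(x$edges, path)
  if (!is.null(nodes_path)) {
    readr::write_csv(x$nodes, nodes_path)
  }
  invisible(path)
}

#' @rdname read_connectome
#' @export
read_connectome_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  ea <- igraph::edge_attr(g)
  if (!all(c("n", "l") %in% names(ea))) {
    rlang::abort("GraphML file must carry edge attributes `n` and `l`",
      class = "braidr_invalid_input"
    )
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  va <- igraph::vertex_attr(g)
  labels <- if (!is.null(va$label)) {
    va$label
  } else if (!is.null(va$name)) {
    va$name
  } else {
    paste0("node", seq_len(igraph::vcount(g)) - 1)
  }
  nodes <- tibble::tibble(id = seq_len(igraph::vcount(g)) - 1L, label = labels)
  edges <- tibble::tibble(
    i = nodes$id[el[, 1]], j = nodes$id[el[, 2]],
    n = as.numeric(ea$n), l = as.numeric(ea$l)
  )
  connectome(edges, nodes)
}

#' @rdname read_connectome
#' @export
write_connectome_graphml <- function(x, path) {
  x <- as_connectome(x)
  g <- igraph::graph_from_data_frame(
    d = data.frame(
      from = as.character(x$edges$i), to = as.character(x$edges$j),
      n = x$edges$n, l = x$edges$l
    ),
    directed = FALSE,
    vertices = data.frame(
      name = as.character(x$nodes$id),
      label = x$nodes$label
    )
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a matrix as dense CSV for audit
#'
#' Writes any of the package's matrices (weight matrices, Laplacians,
#' crossing-time matrices) as a dense CSV with row names in the first
#' column.
#'
#' @param m A matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  stopifnot(is.matrix(m))
  m <- unclass_laplacian(m)
  df <- as.data.frame(m)
  if (is.null(rownames(m))) rownames(df) <- seq_len(nrow(m))
  utils::write.csv(df, path, row.names = TRUE)
  invisible(path)
}

#' Export a trajectory or regional series as tidy TSV
#'
#' Long format with columns `time`, `node` (or `region`), `p`, `q`.
#'
#' @param x A `spread_trajectory` or `regional_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series_tsv <- function(x, path) {
  readr::write_tsv(generics::tidy(x), path)
  invisible(path)
}
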