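#' Build a connectome from an edge list
#'
#' A connectome is an undirected weighted graph whose nodes are anatomical
#' regions of interest and whose edges carry two attributes: the fiber count
#' `n` (dimensionless, >= 0) and the mean fiber length `l` (mm, > 0). The
#' edge table is the primary representation; a companion node table maps node
#' ids to anatomical labels.
#'
#' Directed duplicates (both `(i, j)` and `(j, i)` present) are symmetrized by
#' averaging `n` and `l` across the two orientations, with a message.
#' Self-loops are dropped with a warning.
#'
#' @param edges A data frame with columns `i`, `j` (node ids), `n`
#'   (fiber count) and `l` (fiber length, mm).
#' @param nodes Optional data frame with columns `id` and `label`. When
#'   omitted, nodes are inferred from the edge list and labelled
#'   `"node<id>"`. Node ids may be any integers (files conventionally use
#'   0-based ids); matrix rows follow the order of the node table.
#' @return An object of class `connectome`: a list with tibbles `$nodes`
#'   (`id`, `label`) and `$edges` (`i`, `j`, `n`, `l`, stored with `i`
#'   preceding `j` in node-table order).
#' @examples
#' edges <- tibble::tibble(i = c(0, 0), j = c(1, 2), n = c(5, 3), l = c(40, 20))
#' connectome(edges)
#' @export
connectome <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  required <- c("i", "j", "n", "l")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("edge table is missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "braidr_invalid_input"
    )
  }
  edges <- dplyr::select(edges, dplyr::all_of(required))
  if (any(!is.finite(edges$n)) || any(edges$n < 0)) {
    rlang::abort("fiber counts n must be finite and >= 0", class = "braidr_invalid_input")
  }
  if (any(!is.finite(edges$l)) || any(edges$l <= 0)) {
    rlang::abort("fiber lengths l must be finite and > 0", class = "braidr_invalid_input")
  }

  loops <- edges$i == edges$j
  if (any(loops)) {
    rlang::warn(sprintf("dropping %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }

  if (is.null(nodes)) {
    ids <- sort(unique(c(edges$i, edges$j)))
    nodes <- tibble::tibble(id = ids, label = paste0("node", ids))
  } else {
    nodes <- tibble::as_tibble(nodes)
    if (!all(c("id", "label") %in% names(nodes))) {
      rlang::abort("node table needs columns `id` and `label`",
        class = "braidr_invalid_input"
      )
    }
    nodes <- dplyr::select(nodes, dplyr::all_of(c("id", "label")))
    if (anyDuplicated(nodes$id)) {
      rlang::abort("duplicate node ids in node table", class = "braidr_invalid_input")
    }
    unknown <- setdiff(c(edges$i, edges$j), nodes$id)
    if (length(unknown) > 0) {
      rlang::abort(
        paste0("edge list references node id(s) absent from node table: ",
               paste(unknown, collapse = ", ")),
        class = "braidr_invalid_input"
      )
    }
  }

  # canonical orientation: i before j in node-table order
  pos_i <- match(edges$i, nodes$id)
  pos_j <- match(edges$j, nodes$id)
  flip <- pos_i > pos_j
  edges[flip, c("i", "j")] <- edges[flip, c("j", "i")]

  key <- paste(edges$i, edges$j, sep = "\r")
  if (anyDuplicated(key)) {
    rlang::inform("symmetrizing duplicated edge orientations by averaging n and l")
    edges <- edges |>
      dplyr::group_by(.data$i, .data$j) |>
      dplyr::summarise(n = mean(.data$n), l = mean(.data$l), .groups = "drop")
  }
  edges <- dplyr::arrange(edges, match(.data$i, nodes$id), match(.data$j, nodes$id))

  structure(list(nodes = nodes, edges = edges), class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf(
    "<connectome> %d nodes, %d undirected edges\n",
    nrow(x$nodes), nrow(x$edges)
  ))
  print(x$edges, n = 6)
  invisible(x)
}

#' @export
format.connectome <- function(x, ...) {
  sprintf("<connectome: %d nodes, %d edges>", nrow(x$nodes), nrow(x$edges))
}

#' Tidy a connectome into its edge table
#'
#' @param x A [connectome()].
#' @param ... Unused.
#' @return The edge tibble (`i`, `j`, `n`, `l`).
#' @export
tidy.connectome <- function(x, ...) x$edges

#' One-line summary of a connectome
#'
#' @param x A [connectome()].
#' @param ... Unused.
#' @return A one-row tibble with node, edge, and component counts.
#' @export
glance.connectome <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_components = n_components(x)
  )
}

as_connectome <- function(x) {
  if (inherits(x, "connectome")) {
    return(x)
  }
  if (is.data.frame(x)) {
    return(connectome(x))
  }
  rlang::abort("expected a connectome or an edge-list data frame",
    class = "braidr_invalid_input"
  )
}

# number of connected components, counting isolated nodes
n_components <- function(x) {
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(x$edges$i), to = as.character(x$edges$j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(x$nodes$id))
  )
  igraph::count_components(g)
}

#' Number of nodes in a connectome
#' @param x A [connectome()].
#' @return Integer node count.
#' @export
n_nodes <- function(x) nrow(as_connectome(x)$nodes)
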