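#' The four-node worked example
#'
#' A deterministic toy network used throughout the documentation and tests:
#' four nodes on a cycle 1-2-4-3-1, with edge lengths `l_12 = 40` mm and
#' 20 mm elsewhere, and fiber counts chosen so that the diffusive (DW)
#' weight matrix is exactly
#' `W_12 = 3.125e-7`, `W_13 = 5e-6`, `W_24 = 1e-5`, `W_34 = 1.5e-4`
#' (zero elsewhere). Regions are singletons I..IV and the canonical model
#' parameters are `ln(beta) = 3.897`, `delta = 1`, with total seed mass
#' 0.005 placed on node 1 (region I). At these parameters the seed staging
#' is I -> III -> II -> IV at low thresholds and I -> III -> IV -> II at
#' high thresholds.
#'
#' @return A list with elements `connectome`, `weights` (the DW matrix),
#'   `laplacian` (standard Laplacian of the DW weights), `partition`, and
#'   `params` (list with `beta`, `ln_beta`, `delta`, `seed_mass`,
#'   `seed_region`).
#' @export
four_node_example <- function() {
  lengths <- c(40, 20, 20, 20)
  w_dw <- c(3.125e-7, 5e-6, 1e-5, 1.5e-4)
  edges <- tibble::tibble(
    i = c(1L, 1L, 2L, 3L),
    j = c(2L, 3L, 4L, 4L),
    n = w_dw * lengths^2, # fiber counts back-computed from the DW weights
    l = lengths
  )
  nodes <- tibble::tibble(id = 1:4, label = paste0("node", 1:4))
  cx <- connectome(edges, nodes)
  W <- weight_matrix(cx, "DW")
  list(
    connectome = cx,
    weights = W,
    laplacian = graph_laplacian(W),
    partition = region_partition(list(1L, 2L, 3L, 4L)),
    params = list(
      beta = exp(3.897), ln_beta = 3.897, delta = 1,
      seed_mass = 0.005, seed_region = 1L
    )
  )
}

#' Generate synthetic connectomes
#'
#' Reproducible random test networks. `"random_geometric"` places nodes
#' uniformly in the unit square and connects pairs within a radius scaled
#' so the graph is connected with heterogeneous degrees (regenerated, from
#' the same deterministic stream, until connected); edge lengths are the
#' Euclidean distances in mm (unit square = 100 mm) and fiber counts are
#' drawn log-uniformly. `"regular_ring"` gives a d-regular circulant (every
#' node linked to its d/2 nearest neighbors on each side), the canonical
#' degree-homogeneous case. `"star"` gives a hub with `n - 1` leaves.
#' `"four_node"` returns the deterministic worked example's connectome.
#'
#' The RNG state is saved and restored; the same `seed` always yields the
#' same connectome.
#'
#' @param kind One of `"random_geometric"`, `"regular_ring"`, `"star"`,
#'   `"four_node"`.
#' @param n Number of nodes (>= 2).
#' @param seed Integer seed; fully determines the output.
#' @param d Even degree for `"regular_ring"`.
#' @param radius Connection radius for `"random_geometric"`; default scales
#'   as `1.2 * sqrt(log(n) / n)`.
#' @param max_tries Retries for the connectivity rejection loop.
#' @return A [connectome()].
#' @export
random_connectome <- function(kind = c("random_geometric", "regular_ring", "star", "four_node"),
                              n = 20, seed = 1, d = 4, radius = NULL,
                              max_tries = 100) {
  kind <- match.arg(kind)
  if (kind == "four_node") {
    return(four_node_example()$connectome)
  }
  if (n < 2) {
    rlang::abort("need n >= 2 nodes", class = "braidr_invalid_input")
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  nodes <- tibble::tibble(id = 0:(n - 1), label = paste0("node", 0:(n - 1)))

  if (kind == "regular_ring") {
    if (d %% 2 != 0 || d >= n) {
      rlang::abort("regular_ring needs even d < n", class = "braidr_invalid_input")
    }
    pairs <- list()
    for (v in 0:(n - 1)) {
      for (s in seq_len(d / 2)) {
        u <- (v + s) %% n
        pairs[[length(pairs) + 1]] <- c(v, u)
      }
    }
    e <- do.call(rbind, pairs)
    edges <- tibble::tibble(
      i = e[, 1], j = e[, 2],
      n = round(stats::runif(nrow(e), 10, 100)),
      l = stats::runif(nrow(e), 10, 100)
    )
    return(connectome(edges, nodes))
  }

  if (kind == "star") {
    edges <- tibble::tibble(
      i = 0L, j = 1:(n - 1),
      n = round(stats::runif(n - 1, 10, 100)),
      l = stats::runif(n - 1, 10, 100)
    )
    return(connectome(edges, nodes))
  }

  # random geometric graph, rejected until connected
  r <- if (is.null(radius)) 1.2 * sqrt(log(n) / n) else radius
  for (try in seq_len(max_tries)) {
    xy <- matrix(stats::runif(2 * n), ncol = 2)
    dm <- as.matrix(stats::dist(xy))
    adj <- dm <= r & upper.tri(dm)
    idx <- which(adj, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    edges <- tibble::tibble(
      i = nodes$id[idx[, 1]], j = nodes$id[idx[, 2]],
      n = round(exp(stats::runif(nrow(idx), log(10), log(1000)))),
      l = pmax(dm[idx] * 100, 1) # unit square = 100 mm
    )
    cx <- connectome(edges, nodes)
    if (n_components(cx) == 1) {
      return(cx)
    }
  }
  rlang::abort(
    sprintf("no connected geometric graph found in %d tries; increase radius", max_tries),
    class = "braidr_invalid_input"
  )
}
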