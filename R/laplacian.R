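#' Edge weighting schemes for the graph Laplacian
#'
#' Three weighting schemes from the network-neurodegeneration literature map
#' fiber count `n_ij` and fiber length `l_ij` to an adjacency weight:
#' length-free `W_ij = n_ij` (LW), ballistic `W_ij = n_ij / l_ij` (BW), and
#' diffusive `W_ij = n_ij / l_ij^2` (DW). The diffusive scheme discounts long
#' tracts most strongly and corresponds to graph diffusion with
#' length-rescaled conductances.
#'
#' @param x A [connectome()] or an edge-list data frame.
#' @param scheme `"LW"`, `"BW"`, or `"DW"`.
#' @return A dense symmetric N x N matrix with zero diagonal, node labels as
#'   dimnames, and attribute `scheme`.
#' @examples
#' cx <- four_node_example()$connectome
#' weight_matrix(cx, "DW")[1, 2] # 3.125e-7
#' @export
weight_matrix <- function(x, scheme = c("LW", "BW", "DW")) {
  x <- as_connectome(x)
  scheme <- match.arg(scheme)
  e <- x$edges
  if (scheme %in% c("BW", "DW")) {
    bad <- which(!is.finite(e$l) | e$l <= 0)
    if (length(bad) > 0) {
      rlang::abort(
        sprintf(
          "scheme %s needs positive fiber lengths; offending edge (%s, %s) has l = %g",
          scheme, e$i[bad[1]], e$j[bad[1]], e$l[bad[1]]
        ),
        class = "braidr_invalid_input"
      )
    }
  }
  w <- switch(scheme,
    LW = e$n,
    BW = e$n / e$l,
    DW = e$n / e$l^2
  )
  N <- nrow(x$nodes)
  W <- matrix(0, N, N, dimnames = list(x$nodes$label, x$nodes$label))
  pi <- match(e$i, x$nodes$id)
  pj <- match(e$j, x$nodes$id)
  W[cbind(pi, pj)] <- w
  W[cbind(pj, pi)] <- w
  attr(W, "scheme") <- scheme
  W
}

#' The parametrized graph-Laplacian family
#'
#' Builds `L = D^(1-a-b) - D^(-a) W D^(-b)` where `D` is the diagonal
#' strength matrix `D_ii = sum_j W_ij`. The choice `a = b = 0` gives the
#' standard graph Laplacian `D - W`; `a = b = 1/2` gives the symmetric
#' normalized Laplacian; `(1, 0)` and `(0, 1)` give the random-walk forms.
#'
#' For any parameters other than `(0, 0)` a zero or negative power of the
#' degree is required, so every node must have positive strength.
#'
#' @param W A symmetric nonnegative weight matrix (see [weight_matrix()]).
#' @param a,b Family parameters, each in `[0, 1]` with `a + b <= 1`.
#' @return An N x N matrix of class `graph_laplacian` with attributes `a`,
#'   `b`, and `degree` (the diagonal of `D`).
#' @examples
#' W <- matrix(c(0, 1, 1, 0), 2, 2)
#' graph_laplacian(W) # [[1, -1], [-1, 1]]
#' @export
graph_laplacian <- function(W, a = 0, b = 0) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (max(abs(W - t(W))) > 1e-12 * max(1, max(abs(W)))) {
    rlang::abort("weight matrix must be symmetric", class = "braidr_invalid_input")
  }
  if (any(W < 0)) {
    rlang::abort("weight matrix must be nonnegative", class = "braidr_invalid_input")
  }
  if (a < 0 || a > 1 || b < 0 || b > 1 || a + b > 1 + 1e-12) {
    rlang::abort("need a, b in [0, 1] with a + b <= 1", class = "braidr_invalid_input")
  }
  d <- rowSums(W)
  if (a == 0 && b == 0) {
    L <- diag(d, nrow = nrow(W)) - W
  } else {
    zero_deg <- which(d <= 0)
    if (length(zero_deg) > 0) {
      rlang::abort(
        sprintf(
          "node %s has zero strength; degree powers for (a, b) = (%g, %g) are undefined",
          paste(zero_deg, collapse = ", "), a, b
        ),
        class = "braidr_degenerate_degree"
      )
    }
    L <- diag(d^(1 - a - b), nrow = nrow(W)) -
      (d^(-a)) * W %*% diag(d^(-b), nrow = nrow(W))
  }
  dimnames(L) <- dimnames(W)
  structure(L, a = a, b = b, degree = d, class = c("graph_laplacian", "matrix", "array"))
}

#' @export
print.graph_laplacian <- function(x, ...) {
  cat(sprintf(
    "<graph_laplacian> %d x %d, (a, b) = (%g, %g)\n",
    nrow(x), ncol(x), attr(x, "a"), attr(x, "b")
  ))
  print(unclass_laplacian(x))
  invisible(x)
}

unclass_laplacian <- function(L) {
  attributes(L) <- list(dim = dim(L), dimnames = dimnames(L))
  L
}

condition_check <- function(sums, L, tol) {
  scale <- max(abs(L), 1e-300)
  max_violation <- max(abs(sums))
  list(ok = max_violation <= tol * max(1, scale), max_violation = max_violation)
}

#' Audit the mass-conservation axiom of a graph Laplacian
#'
#' Diffusive transport must not create or destroy mass: the total
#' concentration is invariant under `dp/dt = -L p` exactly when the left
#' null-vector condition `1 . L = 0` holds, i.e. every column of `L` sums to
#' zero. Returns the check outcome and the worst column-sum magnitude.
#'
#' @param L A matrix, typically from [graph_laplacian()].
#' @param tol Tolerance on the column sums, relative to `max(|L|)` (treated
#'   as absolute when `max(|L|) <= 1`).
#' @return A list with `ok` (logical) and `max_violation` (largest absolute
#'   column sum).
#' @export
mass_conservation <- function(L, tol = 1e-10) {
  stopifnot(is.matrix(L), nrow(L) == ncol(L))
  condition_check(colSums(L), L, tol)
}

#' Audit the Fick's-condition axiom of a graph Laplacian
#'
#' Transport must be driven by concentration differences: a spatially uniform
#' state generates no flux exactly when the right null-vector condition
#' `L . 1 = 0` holds, i.e. every row of `L` sums to zero.
#'
#' @inheritParams mass_conservation
#' @return A list with `ok` and `max_violation` (largest absolute row sum).
#' @export
ficks_condition <- function(L, tol = 1e-10) {
  stopifnot(is.matrix(L), nrow(L) == ncol(L))
  condition_check(rowSums(L), L, tol)
}

#' Scan the Laplacian family for physically admissible parameters
#'
#' Evaluates every `(a, b)` grid point with `a + b <= 1`, builds the family
#' member, and records whether it passes the mass-conservation and Fick's
#' condition audits. On degree-heterogeneous graphs only the standard
#' Laplacian `(0, 0)` passes both; on d-regular graphs every family member
#' does.
#'
#' @param W A symmetric nonnegative weight matrix.
#' @param a_values,b_values Numeric grids in `[0, 1]`.
#' @param tol Tolerance forwarded to the two condition audits.
#' @return A tibble with one row per admissible-grid point: `a`, `b`,
#'   `mass_ok`, `ficks_ok`, `mass_violation`, `ficks_violation`, and `ok`
#'   (both conditions hold).
#' @examples
#' W <- weight_matrix(random_connectome("regular_ring", n = 10, d = 4, seed = 1))
#' dplyr::filter(laplacian_scan(W), ok)
#' @export
laplacian_scan <- function(W, a_values = seq(0, 1, by = 0.25),
                           b_values = a_values, tol = 1e-10) {
  grid <- tidyr::expand_grid(a = a_values, b = b_values) |>
    dplyr::filter(.data$a + .data$b <= 1 + 1e-12)
  purrr::pmap(grid, function(a, b) {
    L <- graph_laplacian(W, a, b)
    mc <- mass_conservation(L, tol)
    fc <- ficks_condition(L, tol)
    tibble::tibble(
      a = a, b = b,
      mass_ok = mc$ok, ficks_ok = fc$ok,
      mass_violation = mc$max_violation, ficks_violation = fc$max_violation,
      ok = mc$ok && fc$ok
    )
  }) |>
    purrr::list_rbind()
}
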