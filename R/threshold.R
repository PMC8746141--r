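#' Naive cutoff thresholding
#'
#' Removes every edge whose fiber count `n_ij` falls below an absolute
#' cutoff. Nodes are always retained, so the result can contain isolated
#' nodes; if the thresholded graph is disconnected a warning reports the
#' component count.
#'
#' @param x A [connectome()] or edge-list data frame.
#' @param cutoff Nonnegative cutoff on `n_ij`; edges with `n_ij < cutoff`
#'   are dropped (`cutoff = 0` is the identity).
#' @return A thresholded [connectome()] with the same node table.
#' @export
threshold_naive <- function(x, cutoff) {
  x <- as_connectome(x)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 0) {
    rlang::abort("cutoff must be a single nonnegative number",
      class = "braidr_invalid_input"
    )
  }
  out <- x
  out$edges <- x$edges[x$edges$n >= cutoff, , drop = FALSE]
  warn_if_disconnected(out)
  out
}

#' Disparity-filter backbone thresholding
#'
#' The disparity filter keeps an edge when its weight is statistically
#' surprising against a null in which each node's strength is split uniformly
#' at random among its `k` edges. Under that null the closed-form p-value of
#' edge `(i, j)` seen from endpoint `i` is
#' `alpha_ij = (1 - w_ij / s_i)^(k_i - 1)`, with `s_i` the node strength and
#' `k_i` the degree. An edge survives when its p-value beats `alpha` at
#' *either* endpoint (OR rule); the single edge of a degree-1 node is always
#' retained, since the null is degenerate there.
#'
#' @param x A [connectome()] or edge-list data frame.
#' @param alpha Significance level in `(0, 1)`.
#' @param scheme Weighting scheme used to score edges (default `"LW"`, i.e.
#'   raw fiber counts).
#' @return A thresholded [connectome()] with the same node table.
#' @export
threshold_disparity <- function(x, alpha, scheme = c("LW", "BW", "DW")) {
  x <- as_connectome(x)
  scheme <- match.arg(scheme)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    rlang::abort("alpha must lie strictly inside (0, 1)",
      class = "braidr_invalid_input"
    )
  }
  e <- x$edges
  if (nrow(e) == 0) {
    return(x)
  }
  w <- switch(scheme, LW = e$n, BW = e$n / e$l, DW = e$n / e$l^2)
  ids <- x$nodes$id
  pi <- match(e$i, ids)
  pj <- match(e$j, ids)
  strength <- numeric(length(ids))
  degree <- integer(length(ids))
  for (r in seq_along(w)) {
    strength[pi[r]] <- strength[pi[r]] + w[r]
    strength[pj[r]] <- strength[pj[r]] + w[r]
    degree[pi[r]] <- degree[pi[r]] + 1L
    degree[pj[r]] <- degree[pj[r]] + 1L
  }
  pval <- function(node, wij) {
    k <- degree[node]
    if (k <= 1) {
      return(-Inf) # degree-1 convention: always keep
    }
    (1 - wij / strength[node])^(k - 1)
  }
  keep <- vapply(seq_along(w), function(r) {
    pval(pi[r], w[r]) < alpha || pval(pj[r], w[r]) < alpha
  }, logical(1))
  out <- x
  out$edges <- e[keep, , drop = FALSE]
  warn_if_disconnected(out)
  out
}

#' Pluggable backbone-thresholding dispatcher
#'
#' Dispatches to a named built-in backbone method or to a user-supplied
#' function. Built-ins are `"naive"` ([threshold_naive()]) and `"disparity"`
#' ([threshold_disparity()]). The published doubly-stochastic (`"ds"`),
#' high-salience-skeleton (`"hss"`) and noise-corrected (`"nc"`) backbones
#' are recognized names but not implemented here; pass your own
#' `function(connectome, ...) -> connectome` to plug one in.
#'
#' @param x A [connectome()] or edge-list data frame.
#' @param method A method name or a function taking and returning a
#'   connectome.
#' @param ... Forwarded to the method (e.g. `cutoff`, `alpha`).
#' @return A thresholded [connectome()].
#' @export
threshold_backbone <- function(x, method = "naive", ...) {
  x <- as_connectome(x)
  if (is.function(method)) {
    out <- method(x, ...)
    return(as_connectome(out))
  }
  method <- match.arg(method, c("naive", "disparity", "ds", "hss", "nc"))
  switch(method,
    naive = threshold_naive(x, ...),
    disparity = threshold_disparity(x, ...),
    rlang::abort(
      sprintf(paste0(
        "backbone method '%s' is not built in; supply it as a ",
        "function(connectome, ...) -> connectome"
      ), method),
      class = "braidr_invalid_input"
    )
  )
}

warn_if_disconnected <- function(x) {
  nc <- n_components(x)
  if (nc > 1) {
    rlang::warn(sprintf("thresholded connectome has %d components", nc))
  }
  invisible(nc)
}
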