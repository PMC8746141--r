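# Shared fixtures built in code; no files.

# path graph P_n with unit fiber counts and unit lengths
path_connectome <- function(n_nodes = 3, weights = rep(1, n_nodes - 1)) {
  connectome(tibble::tibble(
    i = 0:(n_nodes - 2), j = 1:(n_nodes - 1),
    n = weights, l = rep(1, n_nodes - 1)
  ))
}

# star K_{1, k}: node 0 is the hub
star_connectome <- function(k = 4, weights = rep(1, k)) {
  connectome(tibble::tibble(
    i = rep(0L, k), j = 1:k, n = weights, l = rep(1, k)
  ))
}

# canonical arrow used in pattern strings
arrow <- " \u2192 "
pat <- function(...) paste(c(...), collapse = arrow)

# a regional_series object built from analytic curves, for staging tests
analytic_series <- function(times, P, dP, regions = NULL) {
  P <- as.matrix(P)
  dP <- as.matrix(dP)
  if (is.null(regions)) {
    regions <- as.character(utils::as.roman(seq_len(ncol(P))))
  }
  structure(
    list(
      times = times, regions = regions,
      P = P, Q = P, dP = dP, dQ = dP, settled = TRUE
    ),
    class = "regional_series"
  )
}

# strip the graph_laplacian class/attrs, keeping dim only
unclass_mat <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}
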