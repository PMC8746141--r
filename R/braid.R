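#' Build a braid diagram
#'
#' A braid diagram records, for one fixed set of model parameters, the
#' staging pattern observed at each biomarker threshold. The system is
#' solved once; all thresholds are evaluated from that single trajectory, so
#' there is no re-integration drift between thresholds.
#'
#' @param x A [connectome()] (weighted with `scheme`) or a Laplacian matrix.
#' @param partition A [region_partition()].
#' @param beta Diffusion-to-growth ratio; alternatively give `ln_beta`.
#' @param ln_beta Natural log of `beta` (the conventional sweep scale).
#' @param delta Tangle accumulation rate (used when `marker = "nft"`).
#' @param thresholds Strictly increasing thresholds in `(0, 1)`; default
#'   1% to 99% in 1% steps.
#' @param marker Stage on seed concentration (`"seed"`) or the tangle
#'   marker (`"nft"`).
#' @param seed_mass,seed_region Initial seeding; see [initial_state()].
#' @param scheme Weighting scheme when `x` is a connectome.
#' @param tie_tol Tie tolerance forwarded to [staging_order()].
#' @param ... Further arguments to [simulate_spread()].
#' @return An object of class `braid_diagram`: a list with `thresholds`,
#'   `patterns` (list of [staging_order()] results), the `crossing_table`,
#'   and the run parameters.
#' @examples
#' fx <- four_node_example()
#' bd <- braid_diagram(fx$laplacian, fx$partition,
#'   ln_beta = fx$params$ln_beta, thresholds = c(0.01, 0.05, 0.40, 0.80)
#' )
#' tidy(bd)
#' @export
braid_diagram <- function(x, partition, beta = NULL, ln_beta = NULL, delta = 1,
                          thresholds = seq(0.01, 0.99, by = 0.01),
                          marker = c("seed", "nft"),
                          seed_mass = 0.005, seed_region = 1,
                          scheme = "DW", tie_tol = 1e-9, ...) {
  marker <- match.arg(marker)
  beta <- resolve_beta(beta, ln_beta)
  L <- as_laplacian(x, scheme)
  init <- initial_state(partition, nrow(L), seed_mass, seed_region)
  traj <- simulate_spread(L, beta,
    p0 = init$p0, q0 = init$q0, delta = delta,
    settle = settle_for(thresholds),
    settle_on = if (marker == "nft") "q" else "p",
    partition = partition, ...
  )
  series <- regional_series(traj, partition)
  table <- crossing_times(series, thresholds, marker = marker)
  patterns <- lapply(
    thresholds,
    function(T) staging_order(table, tie_tol = tie_tol, threshold = T)
  )
  structure(
    list(
      thresholds = thresholds, patterns = patterns, crossing_table = table,
      series = series, beta = beta, delta = delta, marker = marker,
      tie_tol = tie_tol
    ),
    class = "braid_diagram"
  )
}

resolve_beta <- function(beta, ln_beta) {
  if (is.null(beta) && is.null(ln_beta)) {
    rlang::abort("give either beta or ln_beta", class = "braidr_invalid_input")
  }
  if (!is.null(beta) && !is.null(ln_beta)) {
    rlang::abort("give only one of beta and ln_beta", class = "braidr_invalid_input")
  }
  if (is.null(beta)) exp(ln_beta) else beta
}

as_laplacian <- function(x, scheme = "DW") {
  if (inherits(x, "connectome") || is.data.frame(x)) {
    return(graph_laplacian(weight_matrix(as_connectome(x), scheme)))
  }
  stopifnot(is.matrix(x))
  x
}

# regional settle level that guarantees the largest threshold is crossable
settle_for <- function(thresholds) min(0.999, max(max(thresholds) + 0.005, 0.995))

#' @export
print.braid_diagram <- function(x, ...) {
  cat(sprintf(
    "<braid_diagram> %d thresholds, beta = %g, marker = %s\n",
    length(x$thresholds), x$beta, x$marker
  ))
  shown <- unique(vapply(x$patterns, function(p) p$string, character(1)))
  cat("  patterns:", paste(shown, collapse = " | "), "\n")
  invisible(x)
}

#' Tidy a braid diagram
#' @param x A `braid_diagram`.
#' @param ... Unused.
#' @return A tibble with one row per (threshold, region): columns
#'   `threshold`, `region`, `rank` (position in the ordering, `NA` when
#'   unreached), `time`, and `pattern` (canonical string).
#' @export
tidy.braid_diagram <- function(x, ...) {
  tm <- attr(x$crossing_table, "matrix")
  purrr::map2(x$thresholds, x$patterns, function(T, pat) {
    k <- which(abs(x$thresholds - T) < 1e-12)[1]
    rank <- rep(NA_integer_, length(pat$regions))
    rank[pat$order] <- seq_along(pat$order)
    tibble::tibble(
      threshold = T,
      region = factor(pat$regions, levels = pat$regions),
      rank = rank,
      time = tm[, k],
      pattern = pat$string
    )
  }) |>
    purrr::list_rbind()
}

#' Build a braid surface
#'
#' A braid surface maps every (swept parameter value, threshold) cell to the
#' identity of the staging pattern observed there. For each parameter value
#' the dynamics are solved once and all thresholds are read off that single
#' trajectory; patterns are then registered in discovery order (sweeping
#' ascending parameter, then ascending threshold), which fixes the pattern
#' ids and plot colors deterministically. Cells whose simulation fails are
#' marked `NA` and reported in `$failures` rather than aborting the sweep.
#'
#' @param x A [connectome()] (weighted with `scheme`) or a Laplacian matrix.
#' @param partition A [region_partition()].
#' @param values Ascending grid of swept parameter values.
#' @param sweep `"ln_beta"` (default) or `"delta"`.
#' @param thresholds Strictly increasing thresholds in `(0, 1)`.
#' @param beta Fixed `beta` when sweeping `delta`.
#' @param delta Fixed `delta` when sweeping `ln_beta` (default 1).
#' @param marker Stage on `"seed"` concentration or the `"nft"` marker
#'   (defaults to `"nft"` when sweeping `delta`).
#' @param seed_mass,seed_region Initial seeding; see [initial_state()].
#' @param scheme Weighting scheme when `x` is a connectome.
#' @param tie_tol Tie tolerance forwarded to [staging_order()].
#' @param cores Number of worker processes for the (embarrassingly
#'   parallel) per-parameter solves; results are collected and ids assigned
#'   in canonical order, so output is identical to a serial run.
#' @param ... Further arguments to [simulate_spread()].
#' @return An object of class `braid_surface`: a list with `param`
#'   (sweep name), `values`, `thresholds`, `ids` (values x thresholds
#'   integer matrix of pattern ids), `registry` (canonical strings in
#'   discovery order), and `failures`.
#' @export
braid_surface <- function(x, partition, values, sweep = c("ln_beta", "delta"),
                          thresholds = seq(0.01, 0.99, by = 0.01),
                          beta = NULL, delta = 1,
                          marker = NULL, seed_mass = 0.005, seed_region = 1,
                          scheme = "DW", tie_tol = 1e-9, cores = 1, ...) {
  sweep <- match.arg(sweep)
  if (length(values) == 0) {
    rlang::abort("parameter grid is empty", class = "braidr_invalid_input")
  }
  if (is.unsorted(values, strictly = TRUE)) {
    rlang::abort("parameter grid must be strictly ascending",
      class = "braidr_invalid_input"
    )
  }
  if (is.null(marker)) marker <- if (sweep == "delta") "nft" else "seed"
  if (sweep == "delta" && is.null(beta)) {
    rlang::abort("sweeping delta needs a fixed beta", class = "braidr_invalid_input")
  }
  L <- as_laplacian(x, scheme)
  init <- initial_state(partition, nrow(L), seed_mass, seed_region)

  solve_cell <- function(v) {
    b <- if (sweep == "ln_beta") exp(v) else beta
    d <- if (sweep == "delta") v else delta
    tryCatch(
      {
        traj <- simulate_spread(L, b,
          p0 = init$p0, q0 = init$q0, delta = d,
          settle = settle_for(thresholds),
          settle_on = if (marker == "nft") "q" else "p",
          partition = partition, ...
        )
        series <- regional_series(traj, partition)
        table <- crossing_times(series, thresholds, marker = marker)
        list(ok = TRUE, patterns = vapply(
          thresholds,
          function(T) staging_order(table, tie_tol = tie_tol, threshold = T)$string,
          character(1)
        ))
      },
      error = function(e) list(ok = FALSE, message = conditionMessage(e))
    )
  }

  results <- if (cores > 1) {
    parallel::mclapply(values, solve_cell, mc.cores = cores)
  } else {
    lapply(values, solve_cell)
  }

  ids <- matrix(NA_integer_, length(values), length(thresholds))
  registry <- character(0)
  failures <- tibble::tibble(value = numeric(0), message = character(0))
  for (i in seq_along(values)) {
    res <- results[[i]]
    if (!isTRUE(res$ok)) {
      failures <- dplyr::bind_rows(failures, tibble::tibble(
        value = values[i],
        message = as.character(res$message)
      ))
      next
    }
    res <- res$patterns
    for (k in seq_along(thresholds)) {
      id <- match(res[k], registry)
      if (is.na(id)) {
        registry <- c(registry, res[k])
        id <- length(registry)
      }
      ids[i, k] <- id
    }
  }

  structure(
    list(
      param = sweep, values = values, thresholds = thresholds,
      ids = ids, registry = registry, failures = failures,
      marker = marker, delta = delta, beta = beta
    ),
    class = "braid_surface"
  )
}

#' @export
print.braid_surface <- function(x, ...) {
  cat(sprintf(
    "<braid_surface> %s grid [%g, %g] (%d points) x %d thresholds; %d pattern(s)\n",
    x$param, min(x$values), max(x$values), length(x$values),
    length(x$thresholds), length(x$registry)
  ))
  for (i in seq_along(x$registry)) {
    cat(sprintf("  [%d] %s\n", i, x$registry[i]))
  }
  if (nrow(x$failures) > 0) {
    cat(sprintf("  %d failed cell row(s)\n", nrow(x$failures)))
  }
  invisible(x)
}

#' Tidy a braid surface into long format
#' @param x A `braid_surface`.
#' @param ... Unused.
#' @return A tibble with columns `param`, `value`, `threshold`,
#'   `pattern_id`, `pattern`.
#' @export
tidy.braid_surface <- function(x, ...) {
  tibble::tibble(
    param = x$param,
    value = rep(x$values, times = length(x$thresholds)),
    threshold = rep(x$thresholds, each = length(x$values)),
    pattern_id = as.vector(x$ids),
    pattern = x$registry[as.vector(x$ids)]
  )
}

#' One-line summary of a braid surface
#' @param x A `braid_surface`.
#' @param ... Unused.
#' @return A one-row tibble: grid dimensions, number of distinct patterns,
#'   failed cells.
#' @export
glance.braid_surface <- function(x, ...) {
  tibble::tibble(
    param = x$param,
    n_values = length(x$values),
    n_thresholds = length(x$thresholds),
    n_patterns = length(x$registry),
    n_failed_cells = sum(is.na(x$ids))
  )
}

#' Pattern prevalence on a braid surface
#'
#' Counts cells and fractional surface areas per registered pattern, and
#' labels each pattern against the staging catalog.
#'
#' @param surface A `braid_surface`.
#' @param catalog Catalog for [classify_pattern()].
#' @return A tibble with columns `pattern_id`, `pattern`, `label`, `cells`,
#'   `area` (fraction of valid cells; areas sum to 1).
#' @export
surface_summary <- function(surface, catalog = pattern_catalog()) {
  stopifnot(inherits(surface, "braid_surface"))
  valid <- sum(!is.na(surface$ids))
  counts <- tabulate(surface$ids, nbins = length(surface$registry))
  tibble::tibble(
    pattern_id = seq_along(surface$registry),
    pattern = surface$registry,
    label = vapply(surface$registry, classify_pattern, character(1), catalog = catalog),
    cells = counts,
    area = counts / valid
  )
}

#' Export / reimport a braid surface
#'
#' `write_braid_surface()` writes `surface.tsv` (columns `value`,
#' `threshold`, `pattern_id`) and `registry.json` (sweep metadata plus the
#' patterns in discovery order) into a directory, creating it if needed.
#' `read_braid_surface()` reconstructs the surface exactly.
#'
#' @param surface A `braid_surface`.
#' @param dir Output directory.
#' @return `write_braid_surface()` returns `dir` invisibly;
#'   `read_braid_surface()` returns a `braid_surface`.
#' @export
write_braid_surface <- function(surface, dir) {
  stopifnot(inherits(surface, "braid_surface"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) {
      rlang::abort(paste0("cannot create output directory: ", dir))
    }
  }
  grid <- tibble::tibble(
    value = rep(surface$values, times = length(surface$thresholds)),
    threshold = rep(surface$thresholds, each = length(surface$values)),
    pattern_id = as.vector(surface$ids)
  )
  readr::write_tsv(grid, file.path(dir, "surface.tsv"))
  jsonlite::write_json(
    list(
      param = surface$param, marker = surface$marker,
      beta = surface$beta, delta = surface$delta,
      registry = as.list(surface$registry),
      failures = surface$failures
    ),
    file.path(dir, "registry.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(dir)
}

#' @rdname write_braid_surface
#' @param dir Directory written by `write_braid_surface()`.
#' @export
read_braid_surface <- function(dir) {
  grid <- readr::read_tsv(file.path(dir, "surface.tsv"),
    show_col_types = FALSE
  )
  meta <- jsonlite::read_json(file.path(dir, "registry.json"),
    simplifyVector = TRUE
  )
  values <- sort(unique(grid$value))
  thresholds <- sort(unique(grid$threshold))
  ids <- matrix(NA_integer_, length(values), length(thresholds))
  ids[cbind(match(grid$value, values), match(grid$threshold, thresholds))] <-
    as.integer(grid$pattern_id)
  failures <- tibble::as_tibble(meta$failures)
  if (nrow(failures) == 0) {
    failures <- tibble::tibble(value = numeric(0), message = character(0))
  }
  structure(
    list(
      param = meta$param, values = values, thresholds = thresholds,
      ids = ids, registry = as.character(meta$registry),
      failures = failures,
      marker = meta$marker,
      delta = if (is.null(meta$delta)) NULL else meta$delta,
      beta = if (is.null(meta$beta)) NULL else meta$beta
    ),
    class = "braid_surface"
  )
}
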