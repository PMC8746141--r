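#' Initial state for the seeding model
#'
#' The total initial seed mass (default 0.005, dimensionless) is split
#' equally over the nodes of the seed region; every other node starts at
#' zero seed concentration, and the tangle marker `q` starts at zero
#' everywhere.
#'
#' @param partition A [region_partition()].
#' @param n_nodes Number of nodes in the network.
#' @param seed_mass Total initial concentration, in `(0, 1)`.
#' @param seed_region Index (or name) of the seeded region; default the
#'   first region (entorhinal cortex in the packaged staging map).
#' @return A list with numeric vectors `p0` and `q0` of length `n_nodes`.
#' @export
initial_state <- function(partition, n_nodes, seed_mass = 0.005, seed_region = 1) {
  stopifnot(inherits(partition, "region_partition"))
  if (!is.numeric(seed_mass) || seed_mass <= 0 || seed_mass >= 1) {
    rlang::abort("seed_mass must lie in (0, 1)", class = "braidr_invalid_input")
  }
  idx <- partition[[seed_region]]
  if (is.null(idx) || length(idx) == 0) {
    rlang::abort("seed region is empty or absent",
      class = "braidr_invalid_partition"
    )
  }
  if (max(idx) > n_nodes) {
    rlang::abort("seed region references nodes beyond n_nodes",
      class = "braidr_invalid_partition"
    )
  }
  p0 <- numeric(n_nodes)
  p0[idx] <- seed_mass / length(idx)
  list(p0 = p0, q0 = numeric(n_nodes))
}

#' Simulate network Fisher-KPP seeding with tangle accumulation
#'
#' Integrates the coupled system
#' \deqn{dp_i/dt = -\beta \sum_j L_{ij} p_j + p_i (1 - p_i)}
#' \deqn{dq_i/dt = \delta \, p_i (1 - q_i)}
#' on a graph with Laplacian `L`. `p` is the seed-competent protein
#' concentration (logistic local growth, rate scaled to 1, plus graph
#' diffusion with rate `beta`); `q` is a monotone tangle-pathology marker
#' accumulating at rate `delta` wherever seed is present. Time is
#' nondimensional throughout.
#'
#' Integration uses an adaptive stiff-capable method (`deSolve::lsoda`).
#' When `t_max` is `NULL` the horizon starts at 10 and doubles until every
#' region (or node, without a partition) has reached `settle`, or `t_cap` is
#' hit; thresholds never reached within the final horizon are later reported
#' as `Inf` crossing times.
#'
#' @param L Graph Laplacian matrix, normally from [graph_laplacian()] with
#'   `(a, b) = (0, 0)`; any other family member triggers a warning since it
#'   violates a transport axiom.
#' @param beta Diffusion-to-growth ratio, > 0 (dimensionless).
#' @param p0,q0 Initial states; `q0` defaults to zeros.
#' @param delta Tangle accumulation rate, >= 0.
#' @param t_max Fixed horizon, or `NULL` for adaptive extension.
#' @param settle Concentration every region must reach before the adaptive
#'   horizon stops growing.
#' @param settle_on State the settle test watches: seed concentration
#'   (`"p"`, default) or the tangle marker (`"q"`, which lags `p`).
#' @param partition Optional [region_partition()] used for the settle test.
#' @param growth Logical; `FALSE` drops the logistic term (pure diffusion),
#'   mainly for conservation checks.
#' @param rtol,atol Solver tolerances. The defaults are tight so that
#'   near-ties between regional crossing times are resolved by the model,
#'   not by integration error.
#' @param n_out Number of stored output times (uniform grid).
#' @param t_cap Hard cap on the adaptive horizon.
#' @return An object of class `spread_trajectory`: a list with `times`,
#'   matrices `p`, `q`, `dp`, `dq` (stored states and their time
#'   derivatives, rows = times), the inputs, and `settled` (logical).
#' @export
simulate_spread <- function(L, beta, p0, q0 = NULL, delta = 1,
                            t_max = NULL, settle = 0.995,
                            settle_on = c("p", "q"), partition = NULL,
                            growth = TRUE, rtol = 1e-8, atol = 1e-10,
                            n_out = 1500, t_cap = 1e6) {
  settle_on <- match.arg(settle_on)
  if (settle_on == "q" && delta <= 0) settle_on <- "p" # q cannot settle
  stopifnot(is.matrix(L), nrow(L) == ncol(L))
  N <- nrow(L)
  stopifnot(length(p0) == N, beta > 0, delta >= 0)
  if (is.null(q0)) q0 <- numeric(N)
  ab <- c(attr(L, "a"), attr(L, "b"))
  if (length(ab) == 2 && any(ab != 0)) {
    rlang::warn(sprintf(
      "Laplacian (a, b) = (%g, %g) violates a transport axiom; (0, 0) is recommended",
      ab[1], ab[2]
    ))
  }

  rhs <- function(t, y, parms) {
    p <- y[1:N]
    q <- y[(N + 1):(2 * N)]
    dp <- -beta * as.vector(L %*% p)
    if (growth) dp <- dp + p * (1 - p)
    dq <- delta * p * (1 - q)
    list(c(dp, dq))
  }

  solve_to <- function(horizon) {
    times <- seq(0, horizon, length.out = n_out)
    sol <- try(
      deSolve::lsoda(
        y = c(p0, q0), times = times, func = rhs, parms = NULL,
        rtol = rtol, atol = atol, maxsteps = 100000
      ),
      silent = TRUE
    )
    if (inherits(sol, "try-error") || nrow(sol) < length(times)) {
      last_t <- if (inherits(sol, "try-error")) NA_real_ else sol[nrow(sol), 1]
      rlang::abort(
        sprintf("integration failed; last accepted time %s", format(last_t)),
        class = "braidr_integration_error", last_time = last_t
      )
    }
    sol
  }

  settled_at <- function(state_mat) {
    final <- state_mat[nrow(state_mat), ]
    if (is.null(partition)) {
      min(final) >= settle
    } else {
      all(vapply(partition, function(v) mean(final[v]), numeric(1)) >= settle)
    }
  }

  watch_cols <- if (settle_on == "p") 1 + 1:N else 1 + N + 1:N
  horizon <- if (is.null(t_max)) 10 else t_max
  repeat {
    sol <- solve_to(horizon)
    if (!is.null(t_max) || !growth) break
    if (settled_at(sol[, watch_cols, drop = FALSE]) || horizon >= t_cap) break
    horizon <- min(2 * horizon, t_cap)
  }

  times <- unname(sol[, 1])
  p <- unname(sol[, 1 + 1:N, drop = FALSE])
  q <- unname(sol[, 1 + N + 1:N, drop = FALSE])
  deriv <- t(apply(cbind(p, q), 1, function(y) rhs(0, y, NULL)[[1]]))
  structure(
    list(
      times = times, p = p, q = q,
      dp = deriv[, 1:N, drop = FALSE], dq = deriv[, N + 1:N, drop = FALSE],
      beta = beta, delta = delta, growth = growth,
      settled = if (growth) settled_at(sol[, watch_cols, drop = FALSE]) else NA
    ),
    class = "spread_trajectory"
  )
}

#' @export
print.spread_trajectory <- function(x, ...) {
  cat(sprintf(
    "<spread_trajectory> %d nodes, %d times on [0, %g], beta = %g, delta = %g\n",
    ncol(x$p), length(x$times), max(x$times), x$beta, x$delta
  ))
  invisible(x)
}

#' Tidy a trajectory into long format
#' @param x A `spread_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `node`, `p`, `q` (`p`, `q` clamped
#'   to `[0, 1]` for reporting).
#' @export
tidy.spread_trajectory <- function(x, ...) {
  N <- ncol(x$p)
  tibble::tibble(
    time = rep(x$times, times = N),
    node = rep(seq_len(N), each = length(x$times)),
    p = clamp01(as.vector(x$p)),
    q = clamp01(as.vector(x$q))
  )
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Average a trajectory over staging regions
#'
#' Computes the regional mean seed concentration
#' `P_j(t) = (1/N_j) sum_{i in V_j} p_i(t)` and its tangle counterpart
#' `Q_j(t)`, where `N_j` is the node count of region j. Reported values are
#' clamped to `[0, 1]`; unclamped values and their derivatives are kept
#' internally for accurate crossing-time localization.
#'
#' @param traj A `spread_trajectory` from [simulate_spread()].
#' @param partition A [region_partition()] of the trajectory's nodes.
#' @return An object of class `regional_series` wrapping matrices `P`, `Q`
#'   (times x regions) with derivative companions; [tidy()] gives the long
#'   tibble (`time`, `region`, `p`, `q`).
#' @export
regional_series <- function(traj, partition) {
  stopifnot(inherits(traj, "spread_trajectory"))
  if (!inherits(partition, "region_partition")) {
    rlang::abort("partition must be a region_partition",
      class = "braidr_invalid_partition"
    )
  }
  N <- ncol(traj$p)
  if (max(unlist(partition)) > N) {
    rlang::abort("partition references nodes beyond the trajectory",
      class = "braidr_invalid_partition"
    )
  }
  avg <- function(m) {
    out <- vapply(partition, function(v) rowMeans(m[, v, drop = FALSE]),
      numeric(nrow(m))
    )
    unname(as.matrix(out))
  }
  structure(
    list(
      times = traj$times, regions = names(partition),
      P = avg(traj$p), Q = avg(traj$q),
      dP = avg(traj$dp), dQ = avg(traj$dq),
      settled = traj$settled
    ),
    class = "regional_series"
  )
}

#' @export
print.regional_series <- function(x, ...) {
  cat(sprintf(
    "<regional_series> %d regions (%s), %d times on [0, %g]\n",
    length(x$regions), paste(x$regions, collapse = ", "),
    length(x$times), max(x$times)
  ))
  invisible(x)
}

#' Tidy regional series into long format
#' @param x A `regional_series`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `region`, `p`, `q`, clamped to
#'   `[0, 1]`.
#' @export
tidy.regional_series <- function(x, ...) {
  J <- length(x$regions)
  tibble::tibble(
    time = rep(x$times, times = J),
    region = factor(rep(x$regions, each = length(x$times)), levels = x$regions),
    p = clamp01(as.vector(x$P)),
    q = clamp01(as.vector(x$Q))
  )
}

#' Closed-form tangle oracle
#'
#' For a known seed trajectory the tangle equation is linear and separable:
#' `q_i(t) = 1 - exp(-delta * int_0^t p_i ds)`. This evaluates that closed
#' form by high-order quadrature (Hermite-corrected trapezoid using the
#' stored derivatives) on the trajectory grid. It is a verification oracle
#' for the coupled solve, computed independently of the ODE integrator's
#' `q` output.
#'
#' @param traj A `spread_trajectory`.
#' @param delta Accumulation rate; defaults to the trajectory's own.
#' @return A times x nodes matrix of oracle `q` values.
#' @export
nft_closed_form <- function(traj, delta = traj$delta) {
  stopifnot(inherits(traj, "spread_trajectory"))
  h <- diff(traj$times)
  # per-interval integral of the cubic Hermite interpolant of p
  seg <- h / 2 * (traj$p[-1, , drop = FALSE] + traj$p[-nrow(traj$p), , drop = FALSE]) +
    h^2 / 12 * (traj$dp[-nrow(traj$p), , drop = FALSE] - traj$dp[-1, , drop = FALSE])
  cum <- apply(rbind(0, seg), 2, cumsum)
  1 - exp(-delta * cum)
}
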