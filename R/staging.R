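ARROW <- " \u2192 " # the " -> " separator used in canonical pattern strings

#' Threshold-crossing times of regional series
#'
#' For each region j and biomarker threshold `T_k` in `(0, 1]`, records the
#' earliest time at which the regional mean concentration reaches `T_k`
#' (closed threshold: a region already at or above `T_k` at t = 0 crosses at
#' time 0). The crossing is bracketed on the stored grid and then localized
#' on the cubic Hermite interpolant (states plus stored derivatives) by
#' bisection to a relative time tolerance of 1e-8. Thresholds never reached
#' within the simulated horizon are recorded as `Inf`.
#'
#' @param series A `regional_series` from [regional_series()].
#' @param thresholds Strictly increasing thresholds in `(0, 1]`.
#' @param marker `"seed"` (concentration `p`, default) or `"nft"`
#'   (tangle marker `q`).
#' @return An object of class `crossing_table`: a tibble with columns
#'   `region`, `threshold`, `time`, and an attribute `matrix` holding the
#'   J x K crossing-time matrix.
#' @export
crossing_times <- function(series, thresholds, marker = c("seed", "nft")) {
  stopifnot(inherits(series, "regional_series"))
  marker <- match.arg(marker)
  if (!is.numeric(thresholds) || length(thresholds) == 0 ||
    any(thresholds <= 0) || any(thresholds > 1) ||
    is.unsorted(thresholds, strictly = TRUE)) {
    rlang::abort("thresholds must be strictly increasing and lie in (0, 1]",
      class = "braidr_invalid_input"
    )
  }
  V <- if (marker == "seed") series$P else series$Q
  dV <- if (marker == "seed") series$dP else series$dQ
  J <- ncol(V)
  tm <- matrix(Inf, J, length(thresholds),
    dimnames = list(series$regions, NULL)
  )
  for (j in seq_len(J)) {
    tm[j, ] <- vapply(
      thresholds,
      function(T) first_crossing(series$times, V[, j], dV[, j], T),
      numeric(1)
    )
  }
  out <- tibble::tibble(
    region = rep(series$regions, times = length(thresholds)),
    threshold = rep(thresholds, each = J),
    time = as.vector(tm)
  )
  structure(out,
    matrix = tm, thresholds = thresholds,
    class = c("crossing_table", class(out))
  )
}

# earliest t with v(t) >= T on the Hermite interpolant of (times, v, dv)
first_crossing <- function(times, v, dv, T) {
  if (v[1] >= T) {
    return(times[1])
  }
  k <- which(v >= T)[1]
  if (is.na(k)) {
    return(Inf)
  }
  a <- times[k - 1]
  b <- times[k]
  h <- b - a
  hermite <- function(t) {
    s <- (t - a) / h
    h00 <- (1 + 2 * s) * (1 - s)^2
    h10 <- s * (1 - s)^2
    h01 <- s^2 * (3 - 2 * s)
    h11 <- s^2 * (s - 1)
    h00 * v[k - 1] + h10 * h * dv[k - 1] + h01 * v[k] + h11 * h * dv[k]
  }
  f <- function(t) hermite(t) - T
  if (f(b) < 0) {
    return(b) # interpolant dips below stored value; stored bracket endpoint
  }
  stats::uniroot(f, c(a, b), tol = max(1e-12, 1e-8 * max(abs(b), 1)))$root
}

#' Order regions by crossing time into a staging pattern
#'
#' Regions with finite crossing times are sorted ascending; times equal
#' within `tie_tol` are flagged as ties and broken by ascending region
#' index. Regions that never reach the threshold (`Inf`) go to the
#' `unreached` set (ascending index) and make the pattern a distinct
#' identity from any completed pattern. The canonical string (e.g.
#' `"I -> III -> II -> IV"`, with a parenthesized unreached suffix when
#' applicable) fully determines pattern equality.
#'
#' @param times Numeric vector of crossing times (may contain `Inf`),
#'   optionally named by region; unnamed vectors get Roman numerals.
#'   A [crossing_times()] table may be given together with `threshold` to
#'   select a column.
#' @param tie_tol Absolute tie tolerance in nondimensional time.
#' @param threshold When `times` is a `crossing_table`, the threshold whose
#'   column to stage.
#' @return An object of class `staging_pattern`: a list with `order`
#'   (indices of reached regions, ascending time), `unreached`, `ties`
#'   (list of index pairs tied within tolerance), `regions`, and `string`.
#' @examples
#' staging_order(c(I = 1, II = 3, III = 2, IV = Inf))
#' @export
staging_order <- function(times, tie_tol = 1e-9, threshold = NULL) {
  if (inherits(times, "crossing_table")) {
    if (is.null(threshold)) {
      rlang::abort("give `threshold` to pick a column of the crossing table",
        class = "braidr_invalid_input"
      )
    }
    tm <- attr(times, "matrix")
    ks <- attr(times, "thresholds")
    k <- which(abs(ks - threshold) < 1e-12)[1]
    if (is.na(k)) {
      rlang::abort("threshold not present in the crossing table",
        class = "braidr_invalid_input"
      )
    }
    times <- tm[, k]
  }
  regions <- names(times)
  if (is.null(regions)) {
    regions <- as.character(utils::as.roman(seq_along(times)))
  }
  times <- as.numeric(times)
  reached <- which(is.finite(times))
  unreached <- which(!is.finite(times))
  ord <- reached[order(times[reached], reached)]
  ties <- list()
  if (length(ord) > 1) {
    # chain adjacent near-equal times into tie clusters, then break each
    # cluster by ascending region index
    cluster_start <- 1
    clusters <- list()
    for (m in seq_len(length(ord) - 1)) {
      if (abs(times[ord[m + 1]] - times[ord[m]]) > tie_tol) {
        clusters[[length(clusters) + 1]] <- cluster_start:m
        cluster_start <- m + 1
      }
    }
    clusters[[length(clusters) + 1]] <- cluster_start:length(ord)
    for (cl in clusters) {
      if (length(cl) > 1) {
        ord[cl] <- sort(ord[cl])
        for (m in cl[-length(cl)]) {
          ties[[length(ties) + 1]] <- c(ord[m], ord[m + 1])
        }
      }
    }
  }
  string <- paste(regions[ord], collapse = ARROW)
  if (length(unreached) > 0) {
    suffix <- paste0("(unreached: ", paste(regions[unreached], collapse = ", "), ")")
    string <- if (nchar(string) > 0) paste(string, suffix) else suffix
  }
  structure(
    list(
      order = ord, unreached = unreached, ties = ties,
      regions = regions, string = string
    ),
    class = "staging_pattern"
  )
}

#' @export
format.staging_pattern <- function(x, ...) x$string

#' @export
print.staging_pattern <- function(x, ...) {
  cat("<staging_pattern>", x$string, "\n")
  if (length(x$ties) > 0) {
    pairs <- vapply(x$ties, function(p) {
      paste(x$regions[p], collapse = " ~ ")
    }, character(1))
    cat("  ties:", paste(pairs, collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
as.character.staging_pattern <- function(x, ...) x$string

#' Catalog of staging patterns of interest
#'
#' The default catalog holds the four five-region computational staging
#' patterns of interest: the progressive (ascending) Braak sequence, the
#' SUVR-suggested early swap of II and III, and the two uncertain
#' late-staging variants that swap IV and V.
#'
#' @return A named character vector of canonical pattern strings.
#' @export
pattern_catalog <- function() {
  c(
    progressive = paste(c("I", "II", "III", "IV", "V"), collapse = ARROW),
    suvr = paste(c("I", "III", "II", "IV", "V"), collapse = ARROW),
    uncertain_progressive = paste(c("I", "II", "III", "V", "IV"), collapse = ARROW),
    uncertain_suvr = paste(c("I", "III", "II", "V", "IV"), collapse = ARROW)
  )
}

#' Classify a staging pattern against a catalog
#'
#' Pure exact-string lookup of the canonical pattern string; anything not in
#' the catalog is `"other"`.
#'
#' @param pattern A `staging_pattern` or a canonical pattern string.
#' @param catalog Named character vector of canonical strings.
#' @return The catalog name, or `"other"`.
#' @export
classify_pattern <- function(pattern, catalog = pattern_catalog()) {
  s <- if (inherits(pattern, "staging_pattern")) pattern$string else as.character(pattern)
  hit <- names(catalog)[match(s, catalog)]
  ifelse(is.na(hit), "other", hit)
}

#' Dispersion of crossing times at each threshold
#'
#' The population standard deviation (divisor J) of the regional crossing
#' times at a threshold. Near-zero values mark race conditions: regimes
#' where regions reach the threshold almost simultaneously and the observed
#' ordering is sensitive to tiny parameter perturbations. The statistic is
#' undefined when any region never crosses (`Inf` entry).
#'
#' @param table A [crossing_times()] table.
#' @param threshold Optional subset of thresholds; default all.
#' @return A tibble with columns `threshold`, `sd_time` (`NA` when
#'   undefined), and `defined`.
#' @export
staging_time_std <- function(table, threshold = NULL) {
  stopifnot(inherits(table, "crossing_table"))
  tm <- attr(table, "matrix")
  ks <- attr(table, "thresholds")
  if (!is.null(threshold)) {
    sel <- vapply(threshold, function(T) which(abs(ks - T) < 1e-12)[1], numeric(1))
    if (anyNA(sel)) {
      rlang::abort("threshold not present in the crossing table",
        class = "braidr_invalid_input"
      )
    }
    tm <- tm[, sel, drop = FALSE]
    ks <- ks[sel]
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  tibble::tibble(
    threshold = ks,
    sd_time = apply(tm, 2, function(x) if (any(!is.finite(x))) NA_real_ else pop_sd(x)),
    defined = apply(tm, 2, function(x) all(is.finite(x)))
  )
}

#' Write a crossing table to TSV
#'
#' Columns `region`, `threshold`, `time`; infinite times are serialized as
#' the literal string `inf`.
#'
#' @param table A [crossing_times()] table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_crossing_table <- function(table, path) {
  stopifnot(inherits(table, "crossing_table"))
  out <- tibble::as_tibble(table)
  out$time <- ifelse(is.finite(out$time), format(out$time, digits = 15), "inf")
  readr::write_tsv(out, path)
  invisible(path)
}
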