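#' Define staging regions as a partition of nodes
#'
#' Staging regions are pairwise-disjoint, nonempty sets of nodes, indexed by
#' Roman numerals in staging order (region I is the seed region by default).
#' Indices refer to matrix rows, i.e. positions in the connectome node table
#' (1-based), not to raw file node ids.
#'
#' @param regions A list of integer vectors of node indices, one per region.
#' @param names Optional region names; defaults to Roman numerals I, II, ...
#' @return An object of class `region_partition`: a named list of integer
#'   vectors.
#' @examples
#' region_partition(list(1, 2, 3, 4))
#' @export
region_partition <- function(regions, names = NULL) {
  if (!is.list(regions) || length(regions) == 0) {
    rlang::abort("regions must be a nonempty list of node-index vectors",
      class = "braidr_invalid_partition"
    )
  }
  regions <- lapply(regions, function(v) sort(unique(as.integer(v))))
  if (any(lengths(regions) == 0)) {
    rlang::abort("every region must contain at least one node",
      class = "braidr_invalid_partition"
    )
  }
  all_nodes <- unlist(regions)
  if (anyDuplicated(all_nodes)) {
    rlang::abort("regions must be pairwise disjoint",
      class = "braidr_invalid_partition"
    )
  }
  if (any(all_nodes < 1)) {
    rlang::abort("node indices are 1-based matrix row positions",
      class = "braidr_invalid_partition"
    )
  }
  if (is.null(names)) {
    names <- as.character(utils::as.roman(seq_along(regions)))
  }
  stopifnot(length(names) == length(regions), !anyDuplicated(names))
  names(regions) <- names
  structure(regions, class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("<region_partition> %d regions\n", length(x)))
  for (nm in names(x)) {
    cat(sprintf("  %-4s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' Tidy a region partition
#' @param x A [region_partition()].
#' @param ... Unused.
#' @return A tibble with columns `region` and `node`.
#' @export
tidy.region_partition <- function(x, ...) {
  tibble::tibble(
    region = rep(names(x), lengths(x)),
    node = unlist(x, use.names = FALSE)
  )
}

#' Build staging regions from anatomical labels
#'
#' Maps a region configuration (region name -> character vector of label
#' substrings) onto a connectome's node labels. Matching is by
#' case-insensitive substring after stripping non-alphanumeric characters,
#' so `"entorhinal"` matches `"ctx-lh-entorhinal"` and
#' `"rostralanteriorcingulate"` matches `"ctx_rh_rostral_anterior_cingulate"`.
#'
#' @param x A [connectome()].
#' @param config A named list of character vectors, or a path to a JSON file
#'   holding one. Defaults to the packaged five-region staging map
#'   (I entorhinal, II hippocampus, III parahippocampal, IV anterior
#'   cingulate, V occipital).
#' @return A [region_partition()].
#' @export
partition_from_labels <- function(x, config = braak_region_config()) {
  x <- as_connectome(x)
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  squash <- function(s) gsub("[^a-z0-9]", "", tolower(s))
  labels <- squash(x$nodes$label)
  regions <- lapply(config, function(patterns) {
    hits <- unique(unlist(lapply(squash(patterns), function(p) {
      which(grepl(p, labels, fixed = TRUE))
    })))
    sort(hits)
  })
  empty <- names(config)[lengths(regions) == 0]
  if (length(empty) > 0) {
    rlang::abort(
      paste0("no node labels matched region(s): ", paste(empty, collapse = ", ")),
      class = "braidr_invalid_partition"
    )
  }
  region_partition(regions, names = names(config))
}

#' Packaged five-region staging configuration
#'
#' The default staging map adapted to connectome regions of interest:
#' I entorhinal cortex; II hippocampus; III parahippocampal gyrus;
#' IV rostral and caudal anterior cingulate; V cuneus, pericalcarine,
#' lateral occipital, and lingual cortex.
#'
#' @return A named list of label substrings, as read from the packaged JSON.
#' @export
braak_region_config <- function() {
  path <- system.file("extdata", "braak_regions.json", package = "braidr")
  jsonlite::read_json(path, simplifyVector = TRUE)
}
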