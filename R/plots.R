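#' Plot a braid surface
#'
#' Raster of the (parameter, threshold) grid colored by staging-pattern id,
#' with colors assigned in discovery order so identical sweeps always get
#' identical palettes.
#'
#' @param object A `braid_surface`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.braid_surface <- function(object, ...) {
  df <- generics::tidy(object)
  df$pattern <- factor(df$pattern, levels = object$registry)
  xlab <- if (object$param == "ln_beta") "threshold T" else "threshold T"
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$threshold, y = .data$value, fill = .data$pattern
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = discovery_palette(length(object$registry))) +
    ggplot2::labs(
      x = xlab,
      y = if (object$param == "ln_beta") expression(ln(beta)) else expression(delta),
      fill = "staging pattern"
    ) +
    ggplot2::theme_minimal()
}

discovery_palette <- function(k) {
  base <- c(
    "#2e7d32", "#c62828", "#1565c0", "#f9a825", "#6a1b9a",
    "#00838f", "#ef6c00", "#4e342e", "#9e9d24", "#283593"
  )
  if (k <= length(base)) {
    return(base[seq_len(k)])
  }
  c(base, grDevices::rainbow(k - length(base)))
}

#' Render a braid surface to an image file
#'
#' @param surface A `braid_surface`.
#' @param path Output path; the extension selects the device (png, pdf,
#'   svg...). Parent directories are created as needed.
#' @param width,height,dpi Passed to [ggplot2::ggsave()].
#' @return `path`, invisibly.
#' @export
render_surface <- function(surface, path, width = 7, height = 5, dpi = 150) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ggplot2::ggsave(path, autoplot(surface),
    width = width, height = height, dpi = dpi
  )
  invisible(path)
}

#' Plot a braid diagram
#'
#' Each region is drawn as a line tracing its position in the staging
#' ordering (abscissa) across thresholds (ordinate); line crossings are the
#' "braids" where the observed ordering changes.
#'
#' @param object A `braid_diagram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.braid_diagram <- function(object, ...) {
  df <- generics::tidy(object)
  df <- df[!is.na(df$rank), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$rank, y = .data$threshold,
    color = .data$region, group = .data$region
  )) +
    ggplot2::geom_path(linewidth = 1) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_x_continuous(breaks = seq_len(max(df$rank))) +
    ggplot2::labs(x = "staging position", y = "threshold T", color = "region") +
    ggplot2::theme_minimal()
}

#' Plot regional time series
#'
#' @param object A `regional_series`.
#' @param marker `"seed"` or `"nft"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.regional_series <- function(object, marker = c("seed", "nft"), ...) {
  marker <- match.arg(marker)
  df <- generics::tidy(object)
  df$y <- if (marker == "seed") df$p else df$q
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time, y = .data$y, color = .data$region
  )) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = "time (nondimensional)",
      y = if (marker == "seed") "regional seed concentration" else "regional NFT marker",
      color = "region"
    ) +
    ggplot2::theme_minimal()
}
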