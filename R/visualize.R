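#' Heatmap of a segment-resolved eRMSF matrix
#'
#' The central visual output: groups (residues or atoms) on the vertical
#' axis, segment index on the horizontal axis, fill color encoding the eRMSF
#' in Angstrom (viridis, low = dark blue, high = yellow). Optional bicubic
#' smoothing upsamples the matrix with separable cubic splines for display
#' only — the numbers stored on the result are never altered by rendering.
#'
#' @param object an [run_ermsf()] result.
#' @param interpolation `"none"` (default, one tile per matrix cell) or
#'   `"bicubic"` (presentation-only smoothing). A 1x1 matrix falls back to
#'   `"none"` with a warning.
#' @param color_scale `NULL` (auto: the matrix range) or a length-2
#'   `c(min, max)` in Angstrom, e.g. from [shared_color_scale()] to compare
#'   several ensembles on one scale. An all-equal matrix gets a degenerate
#'   guard band of 1e-6.
#' @param upsample integer magnification per axis for bicubic smoothing
#'   (default 8).
#' @param ... unused.
#' @return a ggplot object.
#' @export
#' @examples
#' ref <- make_reference_peptide(12)
#' ens <- make_gaussian_ensemble(ref, sigma = seq(0.1, 1.2, length.out = 12),
#'                               n_frames = 100, seed = 9)
#' res <- run_ermsf(ens, selection = "name CA", skip = 10, align = FALSE)
#' autoplot(res)
autoplot.ermsf_result <- function(object,
                                  interpolation = c("none", "bicubic"),
                                  color_scale = NULL, upsample = 8L, ...) {
  interpolation <- match.arg(interpolation)
  m <- object$matrix
  if (interpolation == "bicubic" && (nrow(m) < 2L || ncol(m) < 2L)) {
    warning("bicubic interpolation needs a matrix of at least 2x2; ",
            "falling back to interpolation = 'none'")
    interpolation <- "none"
  }
  limits <- resolve_color_scale(color_scale, m)
  if (interpolation == "none") {
    df <- tidy(object)
    df$y <- as.integer(df$group)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$segment, y = .data$y,
                                          fill = .data$ermsf)) +
      ggplot2::geom_raster()
  } else {
    sm <- bicubic_upsample(m, factor = upsample)
    # clip spline overshoot into the legend range; display-only
    sm$z <- pmin(pmax(sm$z, limits[1]), limits[2])
    df <- data.frame(segment = rep(sm$x, times = length(sm$y)),
                     y = rep(sm$y, each = length(sm$x)),
                     ermsf = as.vector(sm$z))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$segment, y = .data$y,
                                          fill = .data$ermsf)) +
      ggplot2::geom_raster(interpolate = TRUE)
  }
  group_axis <- if (object$provenance$group_level == "atom") {
    "atom"
  } else if (object$provenance$group_level == "region") {
    "region"
  } else {
    "residue"
  }
  ticks <- pretty_group_ticks(object)
  p +
    ggplot2::scale_fill_viridis_c(name = "eRMSF (Å)", limits = limits,
                                  oob = scales_squish) +
    ggplot2::scale_y_continuous(breaks = ticks$at, labels = ticks$label,
                                expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::labs(x = "segment", y = group_axis) +
    ggplot2::theme_minimal()
}

# avoid a hard dependency on the scales package for out-of-bounds squishing
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}

resolve_color_scale <- function(color_scale, m) {
  if (is.null(color_scale)) {
    limits <- range(m)
  } else {
    if (length(color_scale) != 2L || any(!is.finite(color_scale)) ||
        color_scale[1] >= color_scale[2] || any(color_scale < 0)) {
      stop("color_scale must be c(min, max) with 0 <= min < max",
           call. = FALSE)
    }
    limits <- color_scale
  }
  if (diff(limits) <= 0) limits[2] <- limits[1] + 1e-6  # flat matrix guard
  limits
}

# separable bicubic upsampling via stats::spline, row pass then column pass
bicubic_upsample <- function(m, factor = 8L) {
  nr <- nrow(m); nc <- ncol(m)
  xi <- seq(1, nc, length.out = (nc - 1L) * factor + 1L)
  yi <- seq(1, nr, length.out = (nr - 1L) * factor + 1L)
  rows <- t(apply(m, 1L, function(r) {
    stats::spline(seq_len(nc), r, xout = xi, method = "fmm")$y
  }))
  both <- apply(rows, 2L, function(cc) {
    stats::spline(seq_len(nr), cc, xout = yi, method = "fmm")$y
  })
  list(x = xi, y = yi, z = t(matrix(both, ncol = length(xi))))
}

pretty_group_ticks <- function(result, max_ticks = 12L) {
  n <- nrow(result$matrix)
  at <- unique(round(seq(1L, n, length.out = min(n, max_ticks))))
  label <- if (result$provenance$group_level == "residue" &&
               !anyNA(result$groups$resid)) {
    result$groups$resid[at]
  } else {
    rownames(result$matrix)[at]
  }
  list(at = at, label = label)
}

#' Shared color scale across several results
#'
#' Returns `c(0, max)` over the matrices of all supplied results, so that
#' heatmaps of different ensembles can be drawn with identical legend bounds
#' for direct visual comparison of fluctuation magnitudes.
#'
#' @param ... one or more [run_ermsf()] results.
#' @return length-2 numeric vector for the `color_scale` argument of
#'   [autoplot.ermsf_result()] / [render_heatmap()].
#' @export
shared_color_scale <- function(...) {
  results <- list(...)
  if (!length(results)) stop("no results given", call. = FALSE)
  mx <- max(vapply(results, function(r) max(r$matrix), numeric(1)))
  c(0, max(mx, 1e-6))
}

#' Line plot of the average per-group fluctuation profile
#'
#' @param result an [run_ermsf()] result.
#' @return a ggplot object; the title states how the average was formed.
#' @export
plot_profile <- function(result) {
  df <- profile_table(result)
  df$x <- if (!anyNA(df$resid)) df$resid else as.integer(df$group)
  xlab <- if (!anyNA(df$resid)) "residue" else "group"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$average_ermsf)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::geom_point(size = 0.8, color = "#2c7fb8") +
    ggplot2::labs(x = xlab, y = "average RMSF (Å)",
                  title = paste0("average fluctuation per group (",
                                 result$average_mode, ")")) +
    ggplot2::theme_minimal()
}

# choose an available raster/vector device for the requested path
save_plot_file <- function(p, path, width = 7, height = 5) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg" && !capabilities("cairo")) {
    stop("SVG output requires cairo support in this R build", call. = FALSE)
  }
  if (ext == "png" && !capabilities("png")) {
    # headless builds without png support still get a vector figure
    path <- sub("\\.png$", ".pdf", path, ignore.case = TRUE)
  }
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  path
}

#' Render the eRMSF heatmap to an image file with a sidecar data table
#'
#' Writes the heatmap (PNG, SVG or PDF by file extension) plus a tab-separated
#' sidecar table (`<path>.tsv`, wide layout) holding the exact plotted
#' matrix, so every figure is reproducible without image diffing. Rendering
#' never modifies the result object.
#'
#' @inheritParams autoplot.ermsf_result
#' @param result an [run_ermsf()] result.
#' @param path output image path.
#' @return the written image path, invisibly.
#' @export
render_heatmap <- function(result, path, interpolation = c("none", "bicubic"),
                           color_scale = NULL, upsample = 8L) {
  p <- autoplot(result, interpolation = interpolation,
                color_scale = color_scale, upsample = upsample)
  written <- save_plot_file(p, path)
  write_result_table(result, paste0(path, ".tsv"), layout = "wide")
  invisible(written)
}

#' Render the average profile to an image file with a sidecar table
#'
#' @inheritParams render_heatmap
#' @return the written image path, invisibly.
#' @export
render_profile <- function(result, path) {
  p <- plot_profile(result)
  written <- save_plot_file(p, path)
  df <- profile_table(result)
  utils::write.table(
    data.frame(group_label = as.character(df$group),
               average_ermsf_angstrom = signif(df$average_ermsf, 8)),
    paste0(path, ".tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(written)
}
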