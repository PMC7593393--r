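# Topographic map plotting (ggplot2) and map-series figure export.

# Azimuthal-equidistant 2-D head projection: radius = polar angle / 90,
# nose up (+y anterior), right is right.
.project_2d <- function(montage) {
  tibble(
    label = montage$label,
    px = montage$theta / 90 * cos(deg2rad(montage$phi)),
    py = montage$theta / 90 * sin(deg2rad(montage$phi))
  )
}

#' Plot a single scalp topography
#'
#' Spherical-spline interpolation of a map onto a 2-D azimuthal-equidistant
#' head projection (nose up, right is right), with electrode positions and a
#' symmetric diverging color scale.
#'
#' @param values Per-channel map, microvolts.
#' @param montage A `sep_montage`.
#' @param limits Symmetric color limits (`NULL`: +/- max absolute value).
#' @param grid_n Interpolation grid resolution.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_topomap <- function(values, montage, limits = NULL, grid_n = 60,
                         title = NULL) {
  pr <- .project_2d(montage)
  g <- seq(-1.05, 1.05, length.out = grid_n)
  grid <- expand.grid(px = g, py = g)
  r2 <- grid$px^2 + grid$py^2
  inside <- r2 <= 1.05^2
  theta <- sqrt(r2[inside]) * 90
  phi <- rad2deg(atan2(grid$py[inside], grid$px[inside]))
  vals <- spline_interpolate(montage, values, cbind(theta, phi))
  df <- grid[inside, ]
  df$value <- vals
  lim <- limits %||% c(-1, 1) * max(abs(vals), 1e-12)
  circ <- tibble(
    x = cos(seq(0, 2 * pi, length.out = 181)),
    y = sin(seq(0, 2 * pi, length.out = 181))
  )
  nose <- tibble(x = c(-0.08, 0, 0.08), y = c(0.99, 1.1, 0.99))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$px, y = .data$py)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_path(data = circ, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = nose, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(data = pr, ggplot2::aes(x = .data$px, y = .data$py), size = 0.4) +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "white", high = "#b2182b",
      limits = lim, oob = scales_squish, name = "µV"
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::ggtitle(title)
}

# minimal squish (avoids a scales dependency for one helper)
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}

#' Export a topographic map series as figures
#'
#' One topography per `step_ms` from `start_ms` to `end_ms` (shared symmetric
#' color scale across the series), written as PNG files.
#'
#' @param evoked A `sep_evoked` with montage.
#' @param start_ms,end_ms Range, ms (must lie within the time axis).
#' @param step_ms Step between maps, ms.
#' @param out_dir Output directory (created if needed).
#' @param width,height,dpi Device settings passed to [ggplot2::ggsave()].
#' @return Invisibly, the character vector of files written.
#' @export
plot_map_series <- function(evoked, start_ms, end_ms, step_ms = 15,
                            out_dir = ".", width = 3, height = 3, dpi = 96) {
  if (start_ms < min(evoked$time) || end_ms > max(evoked$time)) {
    abort("requested range lies outside the evoked time axis")
  }
  ats <- seq(start_ms, end_ms, by = step_ms)
  idx <- vapply(ats, function(a) which.min(abs(evoked$time - a)), 1L)
  lim <- c(-1, 1) * max(abs(evoked$data[, idx]), 1e-12)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(ats))
  for (i in seq_along(ats)) {
    p <- plot_topomap(evoked$data[, idx[i]], evoked$montage,
      limits = lim,
      title = sprintf("%g ms", ats[i])
    )
    files[i] <- file.path(out_dir, sprintf("map_%04.0fms.png", ats[i] + 1000))
    ggplot2::ggsave(files[i], p, width = width, height = height, dpi = dpi)
  }
  invisible(files)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `sep_rand_test`: p value as a function of time with the significant
#' periods shaded. `sep_evoked`: butterfly plot with the GFP curve.
#' `sep_cv`: cross-validation curve. `sep_microstates`: prototype map grid.
#'
#' @param object The result object.
#' @param alpha Significance level for shading.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-erptopo
NULL

#' @rdname autoplot-erptopo
#' @export
autoplot.sep_rand_test <- function(object, alpha = 0.05, ...) {
  if (!"time_ms" %in% names(object)) {
    return(
      ggplot2::ggplot(object, ggplot2::aes(x = .data$factor, y = .data$p)) +
        ggplot2::geom_col() +
        ggplot2::geom_hline(yintercept = alpha, linetype = 2) +
        ggplot2::theme_minimal()
    )
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ms, y = .data$p)) +
    ggplot2::geom_area(
      data = ~ dplyr::mutate(.x, p = ifelse(.data$p <= alpha, 1, 0)),
      fill = "grey85"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = alpha, linetype = 2) +
    ggplot2::facet_wrap(~factor) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "time (ms)", y = "p") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-erptopo
#' @export
autoplot.sep_evoked <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(
      as_tibble(t(object$data), .name_repair = "minimal"),
      time_ms = object$time
    ),
    -"time_ms",
    names_to = "channel", values_to = "uv"
  )
  gf <- gfp_curve(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$uv, group = .data$channel)) +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::geom_line(
      data = gf, ggplot2::aes(x = .data$time_ms, y = .data$gfp),
      inherit.aes = FALSE, linewidth = 1
    ) +
    ggplot2::labs(x = "time (ms)", y = "µV (GFP bold)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-erptopo
#' @export
autoplot.sep_cv <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$mean_correlation)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "chosen_k"), linetype = 2) +
    ggplot2::labs(x = "number of classes k", y = "split-half prototype correlation") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-erptopo
#' @param montage Montage for prototype maps (required for
#'   `sep_microstates`).
#' @export
autoplot.sep_microstates <- function(object, montage, grid_n = 50, ...) {
  g <- seq(-1.05, 1.05, length.out = grid_n)
  grid <- expand.grid(px = g, py = g)
  inside <- grid$px^2 + grid$py^2 <= 1.05^2
  theta <- sqrt(grid$px^2 + grid$py^2)[inside] * 90
  phi <- rad2deg(atan2(grid$py[inside], grid$px[inside]))
  dfs <- lapply(seq_len(object$k), function(i) {
    v <- spline_interpolate(montage, object$prototypes[i, ], cbind(theta, phi))
    tibble(
      px = grid$px[inside], py = grid$py[inside], value = v,
      class = sprintf("class %d", i)
    )
  })
  df <- dplyr::bind_rows(dfs)
  lim <- c(-1, 1) * max(abs(df$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$px, y = .data$py, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~class, nrow = 1) +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "white", high = "#b2182b", limits = lim,
      name = "a.u."
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
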