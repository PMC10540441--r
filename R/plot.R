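# Semiogram rendering: a radar chart with seven fixed axes, a dashed
# normative ring at zero, one mean polygon plus a translucent min-max band
# per session, and a fill colour driven by the session's speed z-score.

#' Colour encoding the speed z-score
#'
#' Diverging map clipped to z in `[-4, +2]`: deep red at -4 (severely
#' slowed), light grey at 0 (reference speed), blue-green at +2 (faster
#' than reference).
#'
#' @param speed_z Numeric speed z-score(s).
#' @return Hex colour(s).
#' @export
speed_color <- function(speed_z) {
  z <- pmin(pmax(speed_z, -4), 2)
  pal <- grDevices::colorRamp(c("#a50026", "#f46d43", "#eeeeee", "#1a9850"))
  rgb <- pal((z + 4) / 6)
  grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
}

#' Semiogram radar chart
#'
#' Draws one or several session summaries on the seven fixed criterion axes
#' (sturdiness, springiness, steadiness, stability, smoothness,
#' synchronization, symmetry). The dashed black ring marks the normative
#' zero; each session contributes a coloured mean polygon and a translucent
#' band spanning its per-criterion min-max range; the colour encodes the
#' session's mean speed z-score (see [speed_color()]). Scores below the
#' lower radial limit are drawn clipped at the limit and the session is
#' flagged in the legend.
#'
#' @param sessions A `semiogram_session`, a `semiogram`, or a list of
#'   either.
#' @param limits Radial limits in SD units (default `c(-4, 2)`).
#' @return A ggplot object.
#' @export
plot_semiogram <- function(sessions, limits = c(-4, 2)) {
  stopifnot(length(limits) == 2, limits[1] < limits[2])
  sessions <- normalize_sessions(sessions)
  axes <- criterion_order()
  k <- length(axes)

  clip <- function(v) pmin(pmax(v, limits[1]), limits[2])
  layer_tbl <- purrr::imap_dfr(sessions, function(s, i) {
    clipped <- any(s$criteria$min < limits[1])
    label <- paste0(s$label, if (clipped) " (clipped)" else "")
    tibble(
      session = label,
      criterion = factor(s$criteria$criterion, levels = axes),
      axis = seq_len(k),
      mean = clip(s$criteria$mean),
      min = clip(s$criteria$min),
      max = clip(s$criteria$max),
      color = speed_color(s$speed_z)
    )
  })
  close_poly <- function(d) bind_rows(d, mutate(d[1, ], axis = k + 1))
  mean_poly <- layer_tbl |>
    group_by(.data$session) |>
    dplyr::group_modify(~close_poly(.x)) |>
    ungroup()
  ring <- tibble(axis = seq_len(k + 1), r = 0)

  p <- ggplot(mean_poly, aes(x = .data$axis)) +
    ggplot2::geom_ribbon(aes(ymin = .data$min, ymax = .data$max,
                             group = .data$session, fill = .data$color),
                         alpha = 0.25) +
    ggplot2::geom_path(aes(y = .data$mean, group = .data$session,
                           colour = .data$color), linewidth = 0.9) +
    ggplot2::geom_path(data = ring, aes(x = .data$axis, y = .data$r),
                       linetype = "dashed", colour = "black") +
    ggplot2::scale_colour_identity(
      guide = ggplot2::guide_legend(title = "session"),
      labels = unique(mean_poly$session),
      breaks = unique(mean_poly$color)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_x_continuous(breaks = seq_len(k), labels = axes,
                                limits = c(1, k + 1)) +
    ggplot2::scale_y_continuous(limits = limits) +
    ggplot2::coord_polar(start = -pi / 2, direction = 1) +
    ggplot2::labs(x = NULL, y = "z-score (SD units)") +
    ggplot2::theme_minimal()
  p
}

normalize_sessions <- function(sessions) {
  promote <- function(s) {
    if (inherits(s, "semiogram")) {
      s <- session_summary(list(s), label = s$meta$label %||% "trial")
    }
    stopifnot(inherits(s, "semiogram_session"))
    s
  }
  if (inherits(sessions, c("semiogram", "semiogram_session"))) {
    sessions <- list(sessions)
  }
  stopifnot(length(sessions) >= 1)
  lapply(sessions, promote)
}

#' @rdname plot_semiogram
#' @param object,x A `semiogram` or `semiogram_session`.
#' @param ... Passed to [plot_semiogram()].
#' @export
autoplot.semiogram <- function(object, ...) plot_semiogram(object, ...)

#' @rdname plot_semiogram
#' @export
autoplot.semiogram_session <- function(object, ...) plot_semiogram(object, ...)

#' @rdname plot_semiogram
#' @export
plot.semiogram <- function(x, ...) print(plot_semiogram(x, ...))

#' Render a semiogram chart to a file
#'
#' Vector (SVG, PDF) or raster (PNG) output; format follows the file
#' extension. Rendering is a pure function of its inputs.
#'
#' @param sessions As in [plot_semiogram()].
#' @param path Output file ending in `.svg`, `.pdf` or `.png`.
#' @param limits Radial limits in SD units.
#' @param width,height,dpi Device geometry.
#' @return Invisibly, `path`.
#' @export
render_semiogram <- function(sessions, path, limits = c(-4, 2),
                             width = 6, height = 6, dpi = 150) {
  p <- plot_semiogram(sessions, limits = limits)
  ext <- tolower(tools::file_ext(path))
  dev <- switch(ext,
    svg = function(f, ...) grDevices::svg(f, width = width, height = height),
    pdf = function(f, ...) grDevices::pdf(f, width = width, height = height,
                                          useDingbats = FALSE),
    png = function(f, ...) grDevices::png(f, width = width * dpi,
                                          height = height * dpi, res = dpi),
    abort(sprintf("unsupported output format: .%s", ext))
  )
  dev(path)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(path)
}
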