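# Plot-ready data for the three visual elements: mean-presentation
# timeline, bubble-chart points, and demographic pie breakdowns.

#' Mean-presentation timeline of a pattern
#'
#' For each supporting instance, every STI's start and end are offset by
#' the instance's earliest start; offsets are averaged per transaction and
#' then across supporting transactions (the same two-level averaging MMD
#' uses), giving one bar per pattern position.
#'
#' @param tree A `tirp_tree` mined with `keep_instances = TRUE`.
#' @param node Node id.
#' @param center,earlier,later Optional positions used to tag bar roles
#'   for display; untagged bars are `"other"`.
#' @return A tibble with columns `position`, `symbol`, `mean_start`,
#'   `mean_end`, `role`, ordered by position.
#' @export
timeline_layout <- function(tree, node, center = NULL, earlier = NULL,
                            later = NULL) {
  row <- tree_node(tree, node)
  inst <- row$instances[[1]]
  if (is.null(inst) || nrow(inst) == 0L) {
    rlang::abort(paste0("node '", node, "' carries no instances; re-mine with keep_instances = TRUE"),
                 class = "tirpscope_layout_error")
  }
  bars <- inst |>
    dplyr::mutate(off_start = .data$start - min(.data$start),
                  off_end = .data$end - min(.data$start),
                  .by = c("entity_id", "instance")) |>
    dplyr::summarise(off_start = mean(.data$off_start),
                     off_end = mean(.data$off_end),
                     .by = c("entity_id", "position", "symbol")) |>
    dplyr::summarise(mean_start = mean(.data$off_start),
                     mean_end = mean(.data$off_end),
                     .by = c("position", "symbol")) |>
    dplyr::arrange(.data$position)
  role <- rep("other", nrow(bars))
  role[bars$position %in% earlier] <- "earlier"
  role[bars$position %in% later] <- "later"
  role[bars$position %in% center] <- "center"
  bars$role <- role
  bars
}

BUBBLE_METRICS <- c("relative_vs", "mhs", "mmd", "size")

#' Bubble-chart coordinates for extension rows
#'
#' Maps each panel row to a point whose coordinates are two of the row's
#' TIRP metrics and whose color value is a third; rendering maps the color
#' value to darkness monotonically (higher = darker). Relative vertical
#' support is on the `[0, 1]` scale, so a TIRP with 73% relative VS and
#' MHS 2.08 lands on `(0.73, 2.08)` under the default axes.
#'
#' @param rows Extension rows from [forward_lookup()],
#'   [backward_lookup()] or a session panel.
#' @param x_metric,y_metric,color_metric Metric names among
#'   `"relative_vs"`, `"mhs"`, `"mmd"`, `"size"`; `x_metric` and
#'   `y_metric` must differ. Axes are swappable.
#' @return A tibble with columns `x`, `y`, `color_value`, `label`,
#'   `symbol`, `node`.
#' @export
bubble_points <- function(rows, x_metric = "relative_vs", y_metric = "mhs",
                          color_metric = "mmd") {
  for (m in c(x_metric, y_metric, color_metric)) {
    if (!m %in% BUBBLE_METRICS) {
      rlang::abort(paste0("unknown metric '", m, "'; use one of ",
                          paste(BUBBLE_METRICS, collapse = ", ")),
                   class = "tirpscope_config_error")
    }
  }
  if (x_metric == y_metric) {
    rlang::abort("x_metric and y_metric must differ",
                 class = "tirpscope_config_error")
  }
  tibble::tibble(
    x = as.numeric(rows[[x_metric]]),
    y = as.numeric(rows[[y_metric]]),
    color_value = as.numeric(rows[[color_metric]]),
    label = paste0(rows$symbol, " (", rows$node, ")"),
    symbol = rows$symbol,
    node = rows$node
  )
}

#' Demographic breakdown of a pattern's supporting transactions
#'
#' Proportions of a static attribute's values over the pattern's
#' supporting transactions only; transactions without a recorded value are
#' pooled under `"unknown"`. Proportions sum to 1.
#'
#' @param tree A `tirp_tree`.
#' @param node Node id.
#' @param attributes A data frame with columns `entity_id`, `attribute`,
#'   `value`.
#' @param attribute The attribute name to break down by (e.g. `"gender"`).
#' @return A tibble with columns `value`, `n`, `proportion`.
#' @export
demographic_breakdown <- function(tree, node, attributes, attribute) {
  att <- attributes[attributes$attribute == attribute, ]
  if (nrow(att) == 0L) {
    rlang::abort(paste0("attribute '", attribute, "' absent from all transactions"),
                 class = "tirpscope_attribute_error")
  }
  supporters <- tree_node(tree, node)$support[[1]]
  vals <- att$value[match(supporters, att$entity_id)]
  vals[is.na(vals)] <- "unknown"
  tibble::tibble(value = vals) |>
    dplyr::count(.data$value, name = "n") |>
    dplyr::mutate(proportion = .data$n / sum(.data$n))
}

# ---- ggplot2 helpers ------------------------------------------------------

#' Plot a pattern timeline
#' @param bars A [timeline_layout()] result.
#' @return A ggplot object.
#' @export
plot_timeline <- function(bars) {
  ggplot2::ggplot(bars, ggplot2::aes(y = stats::reorder(.data$symbol,
                                                        -.data$position))) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$mean_start, xend = .data$mean_end,
                   yend = stats::reorder(.data$symbol, -.data$position),
                   color = .data$role),
      linewidth = 5, lineend = "butt"
    ) +
    ggplot2::labs(x = "time since pattern start (mean over instances)",
                  y = NULL, color = "role") +
    ggplot2::theme_minimal()
}

#' Plot extension rows as a bubble chart
#' @param rows Extension rows (a panel tibble).
#' @inheritParams bubble_points
#' @return A ggplot object.
#' @export
plot_bubbles <- function(rows, x_metric = "relative_vs", y_metric = "mhs",
                         color_metric = "mmd") {
  pts <- bubble_points(rows, x_metric, y_metric, color_metric)
  ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$color_value), size = 6,
                        alpha = 0.8) +
    ggplot2::scale_color_gradient(low = "#c6dbef", high = "#08306b") +
    ggplot2::labs(x = x_metric, y = y_metric, color = color_metric) +
    ggplot2::theme_minimal()
}

#' Plot a demographic breakdown as a pie chart
#' @param breakdown A [demographic_breakdown()] result.
#' @return A ggplot object.
#' @export
plot_breakdown <- function(breakdown) {
  ggplot2::ggplot(breakdown,
                  ggplot2::aes(x = "", y = .data$proportion,
                               fill = .data$value)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bubble-chart view of a session's panels
#' @param object A `tirp_session`.
#' @param ... Passed to [bubble_points()].
#' @return A ggplot object faceted by panel direction.
#' @export
autoplot.tirp_session <- function(object, ...) {
  rows <- tidy(object)
  if (nrow(rows) == 0L) {
    rlang::abort("both panels are empty; nothing to plot",
                 class = "tirpscope_layout_error")
  }
  pts <- dplyr::bind_cols(bubble_points(rows, ...),
                          direction = rows$direction)
  ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$color_value), size = 6,
                        alpha = 0.8) +
    ggplot2::facet_wrap(~direction) +
    ggplot2::scale_color_gradient(low = "#c6dbef", high = "#08306b") +
    ggplot2::theme_minimal()
}
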