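#' Plot success frequencies by arm and group size
#'
#' @param object A `crd_ctab` success table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.crd_ctab <- function(object, ...) {
  freq <- object |>
    dplyr::group_by(.data$arm, .data$group_size) |>
    dplyr::summarise(
      success_rate = sum(.data$n[.data$success]) / sum(.data$n),
      .groups = "drop"
    )
  ggplot2::ggplot(freq, ggplot2::aes(
    x = factor(.data$group_size), y = .data$success_rate, fill = .data$arm
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1), labels = scales_percent) +
    ggplot2::labs(x = "Group size", y = "Success frequency", fill = NULL) +
    ggplot2::theme_minimal()
}

scales_percent <- function(x) paste0(round(100 * x), "%")

#' Plot a failure significance envelope
#'
#' Shows the lower quantile curve of surplus among unsuccessful
#' random-playing groups; optionally overlays observed group trajectories.
#'
#' @param object A `crd_envelope`.
#' @param trajectories Optional tibble with `round`, `surplus` and a
#'   `group_id` column to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.crd_envelope <- function(object, trajectories = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$round, y = .data$lower)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(
      x = "Round", y = "Investment surplus/deficit",
      title = sprintf("%.0f%% envelope of unsuccessful random play (n = %d)",
                      100 * attr(object, "level"), attr(object, "n_players"))
    ) +
    ggplot2::theme_minimal()
  if (!is.null(trajectories)) {
    p <- p + ggplot2::geom_line(
      data = trajectories,
      ggplot2::aes(group = .data$group_id),
      alpha = 0.4, colour = "steelblue"
    )
  }
  p
}

#' Plot per-type investment trends
#'
#' Mean investment per round by behavioural type, with the fitted linear
#' trend of each type.
#'
#' @param object A `crd_trends` object.
#' @param gameplay The gameplay table the trends were computed from.
#' @param assignment The type assignment used.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.crd_trends <- function(object, gameplay = NULL, assignment = NULL,
                                ...) {
  if (is.null(gameplay) || is.null(assignment)) {
    abort("Provide the `gameplay` and `assignment` used to fit the trends.")
  }
  dat <- gameplay |>
    dplyr::inner_join(assignment[, c("player_id", "type")], by = "player_id") |>
    dplyr::group_by(.data$type, .data$round) |>
    dplyr::summarise(mean_investment = mean(.data$investment),
                     .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$round, y = .data$mean_investment, colour = .data$type
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::labs(x = "Round", y = "Mean investment", colour = "Type") +
    ggplot2::theme_minimal()
}

#' Plot an MCA category map
#'
#' @param object A `crd_mca` solution.
#' @param types Optional type assignment to overlay centroids
#'   (see [category_map()]).
#' @param ... Unused.
#' @return A ggplot of the first two principal dimensions.
#' @export
autoplot.crd_mca <- function(object, types = NULL, ...) {
  if (is.null(types)) {
    dat <- object$col_coords |>
      dplyr::transmute(label = .data$category, kind = "category",
                       dim1 = .data$dim1, dim2 = .data$dim2)
  } else {
    dat <- category_map(object, types)
  }
  pct <- 100 * object$inertias$proportion
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$dim1, y = .data$dim2, colour = .data$kind, label = .data$label
  )) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey85") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey85") +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.7, show.legend = FALSE) +
    ggplot2::labs(
      x = sprintf("Dimension 1 (%.1f%%)", pct[1]),
      y = sprintf("Dimension 2 (%.1f%%)", pct[2]),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
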