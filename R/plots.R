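# ggplot2 views of the main result types.

#' Plot an activation trajectory under a light schedule
#'
#' @param schedule A [light_schedule()].
#' @param kinetics A [kinetic_params()] list.
#' @param by Time resolution of the curve (minutes).
#' @return A ggplot: activation trajectory with illumination segments shaded.
#' @export
plot_pakt <- function(schedule, kinetics, by = 0.1) {
  traj <- pakt_activity(schedule, kinetics, seq(0, schedule$duration, by = by))
  seg <- schedule$segments[schedule$segments$light_on, , drop = FALSE]
  p <- ggplot2::ggplot(traj, ggplot2::aes(x = .data$time, y = .data$activity))
  if (nrow(seg)) {
    p <- p + ggplot2::geom_rect(
      data = seg,
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "#cfe8ff", alpha = 0.6
    )
  }
  p + ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = "time (min)", y = "activation occupancy",
      title = sprintf("%s %s", schedule$pattern, schedule$intensity)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname fuzzy_cmeans
#' @param object An `optophos_fcm` fit (for `autoplot`).
#' @param features The feature tibble the model was fitted on; when supplied,
#'   per-site profiles are drawn coloured by membership, otherwise only the
#'   cluster centres.
#' @export
autoplot.optophos_fcm <- function(object, features = NULL, ...) {
  centers <- as_tibble(object$centers) %>%
    mutate(cluster = factor(row_number())) %>%
    tidyr::pivot_longer(-"cluster", names_to = "feature", values_to = "value") %>%
    mutate(feature = factor(.data$feature, levels = colnames(object$centers)))
  p <- ggplot2::ggplot()
  if (!is.null(features)) {
    hard <- assign_clusters(object)
    lines <- features %>%
      left_join(hard, by = "site_id") %>%
      tidyr::pivot_longer(
        -c("site_id", "cluster", "membership", "unassigned"),
        names_to = "feature", values_to = "value"
      ) %>%
      mutate(feature = factor(.data$feature, levels = colnames(object$centers)))
    p <- p + ggplot2::geom_line(
      data = lines,
      ggplot2::aes(
        x = .data$feature, y = .data$value, group = .data$site_id,
        colour = .data$membership
      ),
      alpha = 0.5
    ) +
      ggplot2::scale_colour_viridis_c(option = "plasma")
  }
  p +
    ggplot2::geom_line(
      data = centers,
      ggplot2::aes(x = .data$feature, y = .data$value, group = 1),
      colour = "black", linewidth = 1
    ) +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "normalised profile") +
    ggplot2::theme_minimal()
}

#' Waterfall plot of correlations to the reference site
#'
#' @param covar Output of [correlate_to_reference()].
#' @param annotations Site-annotation tibble.
#' @param list Flag column to highlight.
#' @param threshold Correlation threshold drawn as a reference line.
#' @return A ggplot.
#' @export
plot_waterfall <- function(covar, annotations, list = "in_pspdb", threshold = 0.85) {
  wf <- waterfall_table(covar, annotations, lists = list)
  ggplot2::ggplot(wf, ggplot2::aes(x = .data$rank, y = .data$r)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data[[list]]), width = 1) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey80", `TRUE` = "#7b3294")) +
    ggplot2::labs(
      x = "sites ranked by correlation", y = "Pearson R to reference"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap-style view of intensity-regulated profile clusters
#'
#' @param x An `optophos_hclust` result.
#' @param ... Unused.
#' @return A ggplot of centred condition profiles grouped by cluster.
#' @export
autoplot.optophos_hclust <- function(x, ...) {
  profiles <- attr(x, "profiles")
  df <- as_tibble(profiles) %>%
    mutate(site_id = rownames(profiles)) %>%
    left_join(as_tibble(x), by = "site_id") %>%
    tidyr::pivot_longer(-c("site_id", "cluster"),
      names_to = "condition", values_to = "value"
    ) %>%
    mutate(condition = factor(.data$condition, levels = colnames(profiles)))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$condition, y = .data$site_id, fill = .data$value
  )) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$cluster), scales = "free_y", space = "free_y") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6),
      axis.text.y = ggplot2::element_blank()
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = "centred log2")
}
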