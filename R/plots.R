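#' Plot relation frequencies by drug class
#'
#' Bar chart of the [relation_frequencies()] table: percentage of each
#' reporting category, one panel per drug. The *before* relation dominates
#' realistic claims data, so the percentage axis is square-root scaled to
#' keep the rare relations visible.
#'
#' @param freq output of [relation_frequencies()].
#' @return A ggplot object.
#' @export
plot_relation_frequencies <- function(freq) {
  lev <- c(
    "not_applicable", "meets", "before", "overlaps",
    "starts", "finishes", "contains", "equals"
  )
  ggplot2::ggplot(
    freq %>% mutate(relation = factor(.data$relation, levels = lev)),
    ggplot2::aes(x = .data$relation, y = .data$pct)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~drug) +
    ggplot2::scale_y_sqrt() +
    ggplot2::labs(
      x = NULL, y = "% of records",
      title = "Temporal relations between consecutive dispensations"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Episode timeline for one or more persons
#'
#' Coverage segments of each dispensation (coloured by drug, one row per
#' person) with episode spans drawn underneath, shaded by episode type.
#'
#' @param episodes an `oat_episodes` object.
#' @param persons optional person ids to show (default: first 12).
#' @return A ggplot object.
#' @export
plot_episode_timeline <- function(episodes, persons = NULL) {
  ep <- as_tibble(episodes)
  recs <- episode_assignments(episodes)
  if (is.null(persons)) persons <- head(unique(ep$person_id), 12)
  ep <- ep %>% filter(.data$person_id %in% persons)
  recs <- recs %>% filter(.data$person_id %in% persons, !.data$excluded)
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = ep,
      ggplot2::aes(
        xmin = day_as_date(.data$start), xmax = day_as_date(.data$end),
        ymin = -0.45, ymax = 0.45, fill = .data$type
      ),
      alpha = 0.25
    ) +
    ggplot2::geom_segment(
      data = recs,
      ggplot2::aes(
        x = day_as_date(.data$start), xend = day_as_date(.data$end),
        y = 0, yend = 0, colour = .data$assigned_drug
      ),
      linewidth = 3
    ) +
    ggplot2::facet_wrap(~person_id, ncol = 1, strip.position = "left") +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(
      x = NULL, y = NULL, colour = "drug", fill = "episode type",
      title = "Dispensation coverage and constructed episodes"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_episode_timeline `autoplot()` method for episode sets.
#' @param object an `oat_episodes` object.
#' @param ... passed to `plot_episode_timeline()`.
#' @method autoplot oat_episodes
#' @export
autoplot.oat_episodes <- function(object, ...) {
  plot_episode_timeline(object, ...)
}
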