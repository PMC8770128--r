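#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_point
#'   geom_col geom_ribbon scale_fill_gradient2 scale_x_log10 scale_y_log10
#'   labs theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Heatmap of lineage coupling z-scores
#'
#' @param object a [coupling_zscores()] result.
#' @param value `"z"` (default) or `"corr"`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot coupling_result
#' @export
autoplot.coupling_result <- function(object, value = c("z", "corr"), ...) {
  value <- match.arg(value)
  m <- if (value == "z") object$z else object$corr
  df <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble(state1 = rownames(m)),
                     as_tibble(as.data.frame(m))),
    -"state1", names_to = "state2", values_to = "value"
  )
  df$state1 <- factor(df$state1, levels = object$states)
  df$state2 <- factor(df$state2, levels = object$states)
  ggplot(df, aes(x = .data$state1, y = .data$state2, fill = .data$value)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                         na.value = "grey90") +
    labs(x = NULL, y = NULL,
         fill = if (value == "z") "coupling z" else "coupling r") +
    theme_minimal()
}

#' Collision curve: mean collisions against labelled-population size
#'
#' Monte-Carlo means with the closed-form expectation overlaid.
#'
#' @param object a [simulate_collisions()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot collision_curve
#' @export
autoplot.collision_curve <- function(object, ...) {
  df <- as_tibble(object)
  df$expected_collisions <- df$n_cells - df$expected_unique
  ggplot(df, aes(x = .data$n_cells)) +
    geom_line(aes(y = .data$expected_collisions), linetype = 2) +
    geom_point(aes(y = .data$mean_collisions)) +
    scale_x_log10() +
    labs(x = "labelled population size",
         y = "mean barcode collisions",
         caption = "points: Monte-Carlo; dashed: closed form") +
    theme_minimal()
}

#' Heatmap of embryonic-to-postnatal mapping fractions
#'
#' @param fractions a [mapping_fractions()] result.
#' @return A ggplot object.
#' @export
plot_mapping_fractions <- function(fractions) {
  assert_columns(fractions,
                 c("embryonic_cluster", "postnatal_cluster", "fraction"))
  ggplot(dplyr::filter(fractions, !is.na(.data$postnatal_cluster)),
         aes(x = .data$postnatal_cluster, y = .data$embryonic_cluster,
             fill = .data$fraction)) +
    geom_tile() +
    scale_fill_gradient2(low = "white", high = "#B2182B", limits = c(0, 1)) +
    labs(x = "postnatal cluster", y = "embryonic cluster",
         fill = "fraction of\nmapped cells") +
    theme_minimal()
}

#' Bar chart of clone intersection counts
#'
#' A compact UpSet-style view: one bar per distinct state set, ordered by
#' clone count.
#'
#' @param intersections a [clone_intersections()] result (the list or its
#'   `intersections` tibble).
#' @return A ggplot object.
#' @export
plot_clone_intersections <- function(intersections) {
  df <- if (is.data.frame(intersections)) intersections
        else intersections$intersections
  assert_columns(df, c("state_set", "n_clones"))
  df$state_set <- stats::reorder(df$state_set, -df$n_clones)
  ggplot(df, aes(x = .data$state_set, y = .data$n_clones)) +
    geom_col() +
    labs(x = "states occupied by clone", y = "clones") +
    theme_minimal()
}
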