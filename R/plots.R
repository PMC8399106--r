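#' Plot a dissolution profile
#'
#' Per-unit release curves (thin lines) with the mean profile overlaid.
#'
#' @param object A [dissolution_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dissolution_profile
#' @export
autoplot.dissolution_profile <- function(object, ...) {
  means <- summarize_profile(object)
  ggplot2::ggplot(object, ggplot2::aes(.data$time_min, .data$release_pct)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$unit), alpha = 0.35) +
    ggplot2::geom_line(
      data = means,
      ggplot2::aes(.data$time_min, .data$mean_release),
      linewidth = 1, colour = "firebrick", inherit.aes = FALSE
    ) +
    ggplot2::labs(
      x = "time (min)", y = "cumulative release (%)",
      title = sprintf("Dissolution profile: %s", unique(object$product))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a swelling / erosion series
#'
#' @param object A `swelling_series` tibble (see [simulate_swelling()]).
#' @param ... Unused.
#' @return A ggplot with swelling and erosion percentages over time.
#' @method autoplot swelling_series
#' @export
autoplot.swelling_series <- function(object, ...) {
  df <- swelling_erosion(object) |>
    tidyr::pivot_longer(c("swelling_pct", "erosion_pct"),
      names_to = "measure", values_to = "percent"
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$percent, colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (h)", y = "percent of initial weight") +
    ggplot2::theme_minimal()
}

#' Compare two mean dissolution profiles
#'
#' Convenience plot of test vs reference mean curves at shared time
#' points, annotated with the similarity factor.
#'
#' @param test,ref [dissolution_profile()]s.
#' @param time_points Times used for the f2 annotation (default
#'   `c(60, 240, 480)`).
#' @return A ggplot.
#' @export
plot_profile_comparison <- function(test, ref, time_points = c(60, 240, 480)) {
  st <- summarize_profile(test)
  sr <- summarize_profile(ref)
  f2 <- f2_mean(
    summarize_profile(test, time_points)$mean_release,
    summarize_profile(ref, time_points)$mean_release
  )
  df <- dplyr::bind_rows(
    dplyr::mutate(st, product = unique(test$product)),
    dplyr::mutate(sr, product = unique(ref$product))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_min, .data$mean_release,
                                   colour = .data$product)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "time (min)", y = "mean cumulative release (%)",
      subtitle = sprintf("f2 at (%s) min: %.2f",
                         paste(time_points, collapse = ", "), f2)
    ) +
    ggplot2::theme_minimal()
}
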