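#' Caterpillar plot of smoothed estimates
#'
#' Areas ranked by posterior median with their 95% credible intervals — the
#' standard companion graph to a smoothed atlas map, showing the precision
#' behind each mapped value.
#'
#' @param object A `smoothed_estimates` tibble.
#' @param ref Reference line (1, or 100 on the display scale).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.smoothed_estimates <- function(object, ref = 1, ...) {
  d <- dplyr::arrange(object, .data$median, .data$area_id)
  d$rank <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$median)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo95, ymax = .data$hi95),
                           colour = "grey60", width = 0) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = ref, linetype = "dashed") +
    ggplot2::labs(x = "Area rank", y = "Smoothed ratio (95% CrI)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bym_fit <- function(object, ...) {
  autoplot.smoothed_estimates(summarize_sir(object), ...)
}

#' @export
autoplot.excess_fit <- function(object, ...) {
  autoplot.smoothed_estimates(summarize_rer(object), ...)
}

#' Choropleth of map categories
#'
#' Draws the area polygons filled by their five-class map category using a
#' diverging palette.
#'
#' @param polygons Tidy polygon coordinates (`area_id`, `part`, `x`, `y`).
#' @param estimates A `smoothed_estimates` tibble.
#' @return A ggplot object.
#' @export
plot_category_map <- function(polygons, estimates) {
  d <- dplyr::left_join(tibble::as_tibble(polygons),
                        estimates[, c("area_id", "category")], by = "area_id")
  d$grp <- paste(d$area_id, d$part)
  pal <- c("well below" = "#2166ac", "below" = "#92c5de",
           "average" = "#f7f7f7", "above" = "#f4a582",
           "well above" = "#b2182b")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, group = .data$grp,
                                  fill = .data$category)) +
    ggplot2::geom_polygon(colour = "grey40", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Box plots of area estimates by stratum
#'
#' @param estimates A `smoothed_estimates` tibble.
#' @param assignment Stratum assignment from [make_stratum_assignment()].
#' @param by Column to stratify on (`"ses_quintile"` or `"rurality"`).
#' @return A ggplot object.
#' @export
plot_stratum_box <- function(estimates, assignment, by = "ses_quintile") {
  m <- match(estimates$area_id, assignment$area_id)
  d <- tibble::tibble(stratum = factor(assignment[[by]][m]),
                      median = estimates$median)
  ggplot2::ggplot(d, ggplot2::aes(y = .data$stratum, x = .data$median)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "Smoothed ratio (area medians)", y = by) +
    ggplot2::theme_minimal()
}
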