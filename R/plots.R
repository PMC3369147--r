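## ggplot2 graphics for coverage results and cohort reports.

#' Bar chart of regional coverage by group
#'
#' Group means with SD error bars for total, anterior/posterior and the
#' four regional coverages.
#'
#' @param result a `cohort_result` run with `include_3d = TRUE`.
#' @return a ggplot object.
#' @export
plot_coverage_by_group <- function(result) {
  s <- result$subjects
  if (!all(coverage_names %in% names(s)))
    stop("result has no 3D coverage columns")
  long <- tidyr::pivot_longer(s[, c("group", coverage_names)],
                              -"group", names_to = "region",
                              values_to = "percent")
  long$region <- factor(long$region, levels = coverage_names)
  summ <- long |>
    dplyr::group_by(.data$region, .data$group) |>
    dplyr::summarise(mean = mean(.data$percent),
                     sd = sd(.data$percent), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$region, y = .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(0.8), width = 0.25) +
    ggplot2::labs(x = NULL, y = "coverage (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter of posterior wall distance against posterior coverage
#'
#' Pooled subjects with the fitted regression line.
#'
#' @param result a `cohort_result` run with `include_3d = TRUE`.
#' @return a ggplot object.
#' @export
plot_pwd_regression <- function(result) {
  s <- result$subjects
  if (!"Post" %in% names(s)) stop("result has no 3D coverage columns")
  fit <- simple_regression(s$posterior_wall_distance, s$Post)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$posterior_wall_distance,
                                  y = .data$Post, colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(intercept = fit$intercept, slope = fit$slope) +
    ggplot2::labs(x = "posterior wall distance (mm)",
                  y = "posterior coverage (%)",
                  subtitle = sprintf("r = %.2f, slope = %.2f, p = %.3g",
                                     fit$pearson_r, fit$slope, fit$p)) +
    ggplot2::theme_minimal()
}

#' Regional coverage bar chart for a single hip
#'
#' @param object a `head_coverage` result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.head_coverage <- function(object, ...) {
  r <- object$report
  r$region <- factor(r$region, levels = r$region)
  ggplot2::ggplot(r, ggplot2::aes(x = .data$region, y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = NULL, y = "coverage (%)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cohort_result <- function(object, ...) plot_coverage_by_group(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
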