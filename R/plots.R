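# Diagnostic figures for each result type.

#' Heatmap of the initialization-sensitivity surface
#'
#' @param object an [init_grid()] result.
#' @param ... unused.
#' @return A ggplot object: achieved similarity over the `(w0, I0)` plane.
#' @method autoplot grid_result
#' @export
autoplot.grid_result <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$w0, y = .data$I0,
                               fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "FC similarity") +
    ggplot2::labs(x = "initial recurrent strength w0",
                  y = "initial subcortical input I0",
                  title = "Sensitivity to parameter initialization") +
    ggplot2::theme_minimal()
}

#' Grouped bar chart of a young-vs-old comparison
#'
#' Mean fitted parameter per group with standard-deviation bars, one panel
#' pair per flagged region.
#'
#' @param object a [compare_groups()] result.
#' @param significant_only show flagged regions only (default TRUE).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, significant_only = TRUE, ...) {
  df <- tibble::as_tibble(object)
  if (significant_only && any(df$significant)) {
    df <- df[df$significant, , drop = FALSE]
  }
  long <- tidyr::pivot_longer(
    df, cols = c("young_mean", "old_mean"), names_to = "group",
    values_to = "mean") |>
    dplyr::mutate(group = sub("_mean", "", .data$group),
                  sd = ifelse(.data$group == "young", .data$young_sd,
                              .data$old_sd))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$roi, y = .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "fitted parameter", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Scatter and polynomial overlays of an age trend
#'
#' Parameter values against age with the first-order fit dashed and the
#' second-order fit solid.
#'
#' @param object a [fit_trends()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot trend_fit
#' @export
autoplot.trend_fit <- function(object, ...) {
  df <- tibble::tibble(age = object$ages, value = object$values)
  grid <- tibble::tibble(age = seq(min(df$age), max(df$age), length.out = 200))
  grid$fit1 <- object$linear[1] + object$linear[2] * grid$age
  grid$fit2 <- object$quadratic[1] + object$quadratic[2] * grid$age +
    object$quadratic[3] * grid$age^2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit1),
                       linetype = "dashed") +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit2)) +
    ggplot2::labs(x = "age (years)", y = object$parameter,
                  title = sprintf("%s / %s: %s", object$roi,
                                  object$parameter, object$label)) +
    ggplot2::theme_minimal()
}
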