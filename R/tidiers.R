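# broom-style tidiers for the package's fitted objects.

#' Tidy a subject fit
#'
#' @param x a [fit_subject()] result.
#' @param ... unused.
#' @return Tibble with one row per region: `roi`, `w`, `I`.
#' @method tidy fit_result
#' @export
tidy.fit_result <- function(x, ...) {
  N <- length(x$params$w)
  tibble::tibble(roi = paste0("R", seq_len(N)), w = x$params$w,
                 I = x$params$I)
}

#' One-row summary of a subject fit
#'
#' @param x a [fit_subject()] result.
#' @param ... unused.
#' @return Tibble with `best_similarity`, `best_iter`, `n_iter`, `G`,
#'   `sigma`.
#' @method glance fit_result
#' @export
glance.fit_result <- function(x, ...) {
  tibble::tibble(best_similarity = max(x$corr_trace, na.rm = TRUE),
                 best_iter = x$best_iter,
                 n_iter = length(x$corr_trace),
                 G = x$params$G, sigma = x$params$sigma)
}

#' Tidy an age-trend fit
#'
#' @param x a [fit_trends()] result.
#' @param ... unused.
#' @return Tibble with one row per coefficient of each polynomial degree.
#' @method tidy trend_fit
#' @export
tidy.trend_fit <- function(x, ...) {
  tibble::tibble(
    degree = c(1L, 1L, 2L, 2L, 2L),
    term = c("intercept", "age", "intercept", "age", "age^2"),
    estimate = c(x$linear, x$quadratic))
}

#' One-row summary of an age-trend fit
#'
#' @param x a [fit_trends()] result.
#' @param ... unused.
#' @return Tibble with `roi`, `parameter`, `slope`, `curvature`,
#'   `rss_linear`, `rss_quadratic`, `label`.
#' @method glance trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  tibble::tibble(roi = x$roi, parameter = x$parameter,
                 slope = x$linear[2], curvature = x$quadratic[3],
                 rss_linear = x$rss_linear,
                 rss_quadratic = x$rss_quadratic, label = x$label)
}

#' One-row summary of an initialization grid
#'
#' @param x an [init_grid()] result.
#' @param ... unused.
#' @return Tibble with the best cell and surface summaries.
#' @method glance grid_result
#' @export
glance.grid_result <- function(x, ...) {
  best <- x[which.max(x$similarity), ]
  tibble::tibble(n_cells = nrow(x), best_w0 = best$w0, best_I0 = best$I0,
                 best_similarity = best$similarity,
                 mean_similarity = mean(x$similarity))
}
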