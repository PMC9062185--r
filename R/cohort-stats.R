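#' Two-sample t-test
#'
#' Welch's unequal-variance t-test by default (the safer choice when group
#' spreads differ), with a pooled-variance option. Thin wrapper over
#' [stats::t.test()] that enforces the zero-variance contract.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @param var_equal pool the variances (classic two-sample t) instead of
#'   Welch.
#' @return A list with `t`, `p` (two-sided), and `df`.
#' @export
ttest_two_sample <- function(sample_a, sample_b, var_equal = FALSE) {
  for (s in list(sample_a, sample_b)) {
    if (length(s) < 2 || !all(is.finite(s))) {
      abort("both samples must be finite with n >= 2")
    }
  }
  if (sd(sample_a) == 0 && sd(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b)) return(list(t = 0, p = 1, df = NA_real_))
    abort("zero variance in both samples")
  }
  ht <- t.test(sample_a, sample_b, var.equal = var_equal)
  list(t = unname(ht$statistic), p = unname(ht$p.value),
       df = unname(ht$parameter))
}

#' Two-sample t-test from summary statistics
#'
#' The same statistic as [ttest_two_sample()] computed from group means,
#' standard deviations, and sizes only — usable directly on published
#' summary rows.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries; `n >= 2`,
#'   `sd > 0`.
#' @param var_equal pooled-variance variant instead of Welch.
#' @return A list with `t`, `p` (two-sided), and `df`.
#' @export
#' @examples
#' ttest_from_summary(0.64, 0.13, 53, 0.44, 0.12, 31)
ttest_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                               var_equal = FALSE) {
  if (n_a < 2 || n_b < 2) abort("group sizes must be >= 2")
  if (sd_a <= 0 || sd_b <= 0) abort("standard deviations must be > 0")
  if (var_equal) {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    va <- sd_a^2 / n_a
    vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  }
  t <- (mean_a - mean_b) / se
  list(t = t, p = 2 * pt(-abs(t), df), df = df)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values via [stats::p.adjust()]; each adjusted value is
#' at least its raw value and at most 1.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
fdr_correct <- function(p_values) {
  if (!is.numeric(p_values) || any(!is.finite(p_values)) ||
      any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Age-group assignment
#'
#' Subjects under 20 are "young", over 60 are "old", and everyone else —
#' including exact boundary ages 20 and 60 — is "mid".
#'
#' @param age numeric vector of ages in years.
#' @return Factor with levels young, mid, old.
#' @export
assign_age_group <- function(age) {
  factor(ifelse(age < 20, "young", ifelse(age > 60, "old", "mid")),
         levels = c("young", "mid", "old"))
}

#' Assemble a cohort table from per-subject fits
#'
#' Joins subject metadata with fitted regional parameters into the long
#' tidy format the group statistics consume: one row per subject x region.
#'
#' @param fits named list (by subject id) of [fit_subject()] results or
#'   [read_fit_result()] lists.
#' @param subjects data frame with columns `id`, `age`, and optionally `sex`.
#' @param roi optional region labels (recycled across subjects).
#' @return A tibble with columns `id`, `age`, `sex`, `group`, `roi`, `w`,
#'   `I`.
#' @export
build_cohort_table <- function(fits, subjects, roi = NULL) {
  missing_ids <- setdiff(as.character(subjects$id), names(fits))
  if (length(missing_ids)) {
    abort(sprintf("missing fits for subject(s): %s",
                  paste(missing_ids, collapse = ", ")))
  }
  purrr::map_dfr(seq_len(nrow(subjects)), function(i) {
    id <- as.character(subjects$id[i])
    p <- fits[[id]]$params
    N <- length(p$w)
    tibble::tibble(
      id = id,
      age = subjects$age[i],
      sex = if ("sex" %in% names(subjects)) subjects$sex[i] else NA_character_,
      roi = roi %||% paste0("R", seq_len(N)),
      w = p$w, I = p$I)
  }) |>
    dplyr::mutate(group = assign_age_group(.data$age), .after = "age")
}

#' Per-region young-vs-old group comparison
#'
#' For each region and requested parameter, tests the young group against the
#' old group with a two-sample t-test (Welch by default), corrects the
#' p-values for multiple comparisons across regions by Benjamini-Hochberg
#' FDR, and flags regions with corrected p below `alpha`. By default the
#' correction is applied separately within each parameter family (`w` and
#' `I` are reported as separate analyses); `fdr_family = "single"` pools
#' them into one family.
#'
#' @param cohort a [build_cohort_table()] tibble (columns `group`, `roi`,
#'   and the parameter columns).
#' @param parameter which fitted parameter(s) to compare.
#' @param alpha significance level on the corrected p-values.
#' @param var_equal pooled-variance t-test instead of Welch.
#' @param fdr_family `"per_parameter"` (default) or `"single"`.
#' @return A `group_comparison` tibble: one row per region x parameter with
#'   group summaries, `t`, `df`, `p`, `p_adj`, `significant`.
#' @export
compare_groups <- function(cohort, parameter = c("w", "I"), alpha = 0.05,
                           var_equal = FALSE,
                           fdr_family = c("per_parameter", "single")) {
  parameter <- match.arg(parameter, several.ok = TRUE)
  fdr_family <- match.arg(fdr_family)
  young <- cohort[cohort$group == "young", , drop = FALSE]
  old <- cohort[cohort$group == "old", , drop = FALSE]
  if (!nrow(young) || !nrow(old)) {
    abort("both a young (< 20 y) and an old (> 60 y) group are required")
  }
  res <- purrr::map_dfr(parameter, function(par) {
    purrr::map_dfr(unique(cohort$roi), function(r) {
      a <- young[[par]][young$roi == r]
      b <- old[[par]][old$roi == r]
      tt <- ttest_two_sample(a, b, var_equal = var_equal)
      tibble::tibble(parameter = par, roi = r,
                     young_n = length(a), young_mean = mean(a),
                     young_sd = sd(a),
                     old_n = length(b), old_mean = mean(b), old_sd = sd(b),
                     t = tt$t, df = tt$df, p = tt$p)
    })
  })
  res <- if (fdr_family == "per_parameter") {
    res |>
      dplyr::group_by(.data$parameter) |>
      dplyr::mutate(p_adj = fdr_correct(.data$p)) |>
      dplyr::ungroup()
  } else {
    dplyr::mutate(res, p_adj = fdr_correct(.data$p))
  }
  res <- dplyr::mutate(res, significant = .data$p_adj < alpha)
  structure(res, alpha = alpha, fdr_family = fdr_family,
            class = c("group_comparison", class(res)))
}

#' Fraction of significant regions with a printable percentage
#'
#' @param n_significant,n_total counts of flagged and tested regions.
#' @param digits decimal places in the formatted percentage.
#' @return A list with `fraction`, `percent` (numeric, on the 0-100 scale),
#'   and `label` (e.g. `"8.5%"`).
#' @export
#' @examples
#' significant_fraction(16, 188)$label
significant_fraction <- function(n_significant, n_total, digits = 1) {
  if (n_total < 1 || n_significant < 0 || n_significant > n_total) {
    abort("need 0 <= n_significant <= n_total")
  }
  frac <- n_significant / n_total
  pct <- round(100 * frac, digits)
  list(fraction = frac, percent = pct,
       label = paste0(formatC(pct, format = "f", digits = digits), "%"))
}

#' Publication-style group-comparison report
#'
#' Formats a [compare_groups()] result in the conventional layout: region
#' name, group means with standard deviations as `"0.64 (± 0.13)"`, and
#' the FDR-corrected p-value, restricted to flagged regions by default.
#'
#' @param comparison a `group_comparison` tibble.
#' @param roi_table optional ROI metadata (columns `abbrev`, `name`) joined
#'   by position against `roi`.
#' @param significant_only keep only flagged rows (default TRUE).
#' @return A tibble with columns `roi`, `parameter`, `young`, `old`,
#'   `p_corrected`.
#' @export
report_comparison <- function(comparison, roi_table = NULL,
                              significant_only = TRUE) {
  df <- tibble::as_tibble(comparison)
  if (significant_only) df <- df[df$significant, , drop = FALSE]
  fmt <- function(m, s) sprintf("%.2f (± %.2f)", m, s)
  out <- tibble::tibble(
    roi = df$roi,
    parameter = df$parameter,
    young = fmt(df$young_mean, df$young_sd),
    old = fmt(df$old_mean, df$old_sd),
    p_corrected = round(df$p_adj, 4))
  if (!is.null(roi_table)) {
    idx <- match(out$roi, roi_table$abbrev)
    out$name <- roi_table$name[idx]
    out <- dplyr::relocate(out, "name")
  }
  out
}

#' Polynomial age-trend fit for one region
#'
#' Ordinary least squares of a fitted parameter on age with first- and
#' second-order polynomials, plus a shape classification of the trajectory
#' (see [classify_trend()]).
#'
#' @param cohort a [build_cohort_table()] tibble.
#' @param roi region label to fit.
#' @param parameter `"w"` or `"I"`.
#' @return An object of class `trend_fit`: both `lm` fits, their
#'   coefficients, residual sums of squares, the data, and the shape
#'   `label`.
#' @export
fit_trends <- function(cohort, roi, parameter = c("w", "I")) {
  parameter <- match.arg(parameter)
  d <- cohort[cohort$roi == roi, , drop = FALSE]
  if (length(unique(d$age)) < 4) abort("need >= 4 subjects with distinct ages")
  df <- data.frame(age = d$age, value = d[[parameter]])
  fit1 <- lm(value ~ age, data = df)
  fit2 <- lm(value ~ age + I(age^2), data = df)
  out <- structure(list(
    roi = roi, parameter = parameter,
    linear = unname(coef(fit1)),            # (intercept, slope)
    quadratic = unname(coef(fit2)),         # (intercept, linear, curvature)
    rss_linear = sum(fit1$residuals^2),
    rss_quadratic = sum(fit2$residuals^2),
    fit1 = fit1, fit2 = fit2,
    ages = df$age, values = df$value),
    class = "trend_fit")
  out$label <- classify_trend(out)
  out
}

#' Classify the shape of an age trajectory
#'
#' Labels a [fit_trends()] result as `"inverted-U"` (negative curvature,
#' vertex inside the observed age range, and a quadratic term that improves
#' on the line by a partial F-test), `"U"` (same with positive curvature),
#' `"linear-decline"` / `"linear-incline"` (significant slope without a
#' useful quadratic), or `"flat"`. "Inside" means between the 10th and 90th
#' percentile of observed ages by default, so a vertex pinned at an extreme
#' does not count as a peak.
#'
#' @param fit a `trend_fit`.
#' @param age_range optional explicit interior interval for the vertex;
#'   defaults to the percentile band of the observed ages.
#' @param vertex_band percentile band defining "interior" (default 0.1-0.9).
#' @param slope_alpha significance level on the linear slope t-test.
#' @param curve_alpha significance level on the partial F-test for the
#'   quadratic term.
#' @return A single string label.
#' @export
classify_trend <- function(fit, age_range = NULL, vertex_band = c(0.1, 0.9),
                           slope_alpha = 0.05, curve_alpha = 0.05) {
  band <- age_range %||% unname(quantile(fit$ages, vertex_band))
  curv <- fit$quadratic[3]
  tss <- sum((fit$values - mean(fit$values))^2)
  n <- length(fit$values)

  # Does the quadratic genuinely improve on the line? Guard against
  # numerically-exact fits where both RSS are rounding noise.
  improves <- FALSE
  if (fit$rss_linear - fit$rss_quadratic > 1e-12 * max(tss, 1e-12) && n > 3) {
    Fstat <- (fit$rss_linear - fit$rss_quadratic) /
      (fit$rss_quadratic / (n - 3))
    pF <- pf(Fstat, 1, n - 3, lower.tail = FALSE)
    improves <- is.finite(Fstat) && !is.na(pF) && pF < curve_alpha
    if (fit$rss_quadratic <= 1e-12 * max(tss, 1e-12)) improves <- TRUE
  }
  if (improves && curv != 0) {
    vertex <- -fit$quadratic[2] / (2 * curv)
    if (vertex >= band[1] && vertex <= band[2]) {
      return(if (curv < 0) "inverted-U" else "U")
    }
  }
  slope <- fit$linear[2]
  sm <- summary(fit$fit1)$coefficients
  p_slope <- if (nrow(sm) >= 2) sm[2, 4] else NA_real_
  if (fit$rss_linear <= 1e-12 * max(tss, 1e-12)) p_slope <- 0 # exact line
  if (!is.na(p_slope) && p_slope < slope_alpha && slope != 0) {
    return(if (slope < 0) "linear-decline" else "linear-incline")
  }
  "flat"
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s / %s: slope %.4g per year, curvature %.3g, label %s\n",
              x$roi, x$parameter, x$linear[2], x$quadratic[3], x$label))
  invisible(x)
}

#' Age-trend summary across all regions
#'
#' Runs [fit_trends()] for every region and returns one tidy row per region.
#'
#' @param cohort a [build_cohort_table()] tibble.
#' @param parameter `"w"` or `"I"`.
#' @param ... passed to [classify_trend()] via refitting.
#' @return A tibble with columns `roi`, `parameter`, `intercept`, `slope`,
#'   `curvature`, `vertex`, `rss_linear`, `rss_quadratic`, `label`.
#' @export
trend_table <- function(cohort, parameter = c("w", "I"), ...) {
  parameter <- match.arg(parameter)
  purrr::map_dfr(unique(cohort$roi), function(r) {
    f <- fit_trends(cohort, r, parameter)
    tibble::tibble(
      roi = r, parameter = parameter,
      intercept = f$linear[1], slope = f$linear[2],
      curvature = f$quadratic[3],
      vertex = if (f$quadratic[3] != 0) -f$quadratic[2] / (2 * f$quadratic[3]) else NA_real_,
      rss_linear = f$rss_linear, rss_quadratic = f$rss_quadratic,
      label = f$label)
  })
}
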