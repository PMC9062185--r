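test_that("two-sample t-test honours its degenerate contracts", {
  r <- ttest_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_error(ttest_two_sample(c(1, 1, 1), c(2, 2, 2)), "zero variance")
  expect_error(ttest_two_sample(1, c(1, 2)), "n >= 2")
  # p decreases monotonically as the groups separate
  a <- c(1, 2, 3)
  ps <- vapply(c(1, 3, 9), function(d) ttest_two_sample(a, a + d)$p,
               numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("t statistics match an explicit Welch formula oracle", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      a <- rnorm(sample(5:30, 1), 1, 2)
      b <- rnorm(sample(5:30, 1), 0.4, 1.3)
    })
    r <- ttest_two_sample(a, b)
    va <- var(a) / length(a); vb <- var(b) / length(b)
    t_star <- (mean(a) - mean(b)) / sqrt(va + vb)
    df_star <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    expect_equal(r$t, t_star, tolerance = 1e-10)
    expect_equal(r$df, df_star, tolerance = 1e-10)
    expect_equal(r$p, 2 * pt(-abs(t_star), df_star), tolerance = 1e-10)
  }
})

test_that("summary-statistic t-test agrees with the raw-data test", {
  # engineer samples with exactly the requested mean and sd
  make <- function(n, mu, s, seed) {
    z <- withr::with_seed(seed, rnorm(n))
    z <- (z - mean(z)) / sd(z)
    mu + s * z
  }
  a <- make(14, 0.8, 0.2, 1)
  b <- make(9, 0.55, 0.12, 2)
  raw <- ttest_two_sample(a, b)
  summ <- ttest_from_summary(0.8, 0.2, 14, 0.55, 0.12, 9)
  expect_equal(raw$t, summ$t, tolerance = 1e-8)
  expect_equal(raw$p, summ$p, tolerance = 1e-8)
  # pooled-variance variant agrees with t.test(var.equal = TRUE)
  rp <- t.test(a, b, var.equal = TRUE)
  sp <- ttest_from_summary(0.8, 0.2, 14, 0.55, 0.12, 9, var_equal = TRUE)
  expect_equal(unname(rp$statistic), sp$t, tolerance = 1e-8)
  expect_equal(ttest_from_summary(1, 0.1, 5, 1, 0.2, 8)$t, 0)
  expect_error(ttest_from_summary(1, 0, 5, 1, 0.2, 8), "> 0")
  expect_error(ttest_from_summary(1, 0.1, 1, 1, 0.2, 8), ">= 2")
})

test_that("BH correction matches a hand case and a sort-cummin oracle", {
  expect_equal(fdr_correct(0.03), 0.03)
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(m / (m:1) * p[o]))[ro]
  }
  for (seed in 1:5) {
    p <- withr::with_seed(seed, runif(37))
    adj <- fdr_correct(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # adjusted values are monotone in raw-p rank
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("age grouping sends boundary ages to the middle group", {
  g <- assign_age_group(c(4, 19.9, 20, 40, 60, 60.1, 85))
  expect_equal(as.character(g),
               c("young", "young", "mid", "mid", "mid", "old", "old"))
})

test_that("group comparison flags planted effects and controls the FDR", {
  n_seeds <- 20
  recovered <- numeric(n_seeds)
  fdp <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    tab <- toy_cohort_table(50, 50, n_roi = 20, delta_w = 1.5 * 0.05,
                            affected = 1:3, sd = 0.05, seed = s)
    cmp <- compare_groups(tab, parameter = "w")
    flags <- cmp$roi[cmp$significant]
    recovered[s] <- length(intersect(flags, paste0("R", 1:3)))
    fdp[s] <- if (length(flags)) {
      length(setdiff(flags, paste0("R", 1:3))) / length(flags)
    } else 0
  }
  expect_gte(mean(recovered), 2)
  expect_lte(mean(fdp), 0.10)
})

test_that("null cohorts almost never produce flags", {
  clean <- vapply(seq_len(20), function(s) {
    tab <- toy_cohort_table(50, 50, n_roi = 20, seed = 100 + s)
    sum(compare_groups(tab, parameter = "w")$significant) == 0
  }, logical(1))
  expect_gte(sum(clean), 18)
})

test_that("identical group values give zero t everywhere", {
  vals <- withr::with_seed(1, rnorm(5 * 4, 0.5, 0.1))
  tab <- purrr::map_dfr(1:10, function(i) {
    tibble::tibble(id = sprintf("S%02d", i),
                   age = if (i <= 5) 10 else 70,
                   group = assign_age_group(if (i <= 5) 10 else 70),
                   roi = paste0("R", 1:4),
                   w = vals[((i - 1) %% 5) * 4 + 1:4], I = 0.3)
  })
  cmp <- compare_groups(tab, parameter = "w")
  expect_equal(cmp$t, rep(0, 4))
  expect_error(compare_groups(tab[tab$group == "young", ], "w"), "required")
})

test_that("comparison results are invariant to region ordering", {
  tab <- toy_cohort_table(20, 20, n_roi = 8, delta_w = 0.12, affected = 1:2,
                          seed = 3)
  cmp1 <- compare_groups(tab, parameter = "w")
  tab_shuffled <- withr::with_seed(4, tab[sample(nrow(tab)), ])
  cmp2 <- compare_groups(tab_shuffled, parameter = "w")
  m <- match(cmp1$roi, cmp2$roi)
  expect_equal(cmp1$p_adj, cmp2$p_adj[m], tolerance = 1e-12)
  expect_equal(cmp1$significant, cmp2$significant[m])
})

test_that("FDR family modes adjust within or across parameter families", {
  tab <- toy_cohort_table(20, 20, n_roi = 6, delta_w = 0.15, affected = 1:2,
                          seed = 5)
  per <- compare_groups(tab, parameter = c("w", "I"))
  expect_setequal(unique(per$parameter), c("w", "I"))
  w_rows <- per[per$parameter == "w", ]
  expect_equal(w_rows$p_adj, fdr_correct(w_rows$p), tolerance = 1e-12)
  single <- compare_groups(tab, parameter = c("w", "I"),
                           fdr_family = "single")
  expect_equal(single$p_adj, fdr_correct(single$p), tolerance = 1e-12)
})

test_that("polynomial fits match the normal equations and label exact shapes", {
  ages <- seq(5, 80, length.out = 30)
  # exact line
  tab_line <- tibble::tibble(id = as.character(seq_along(ages)), age = ages,
                             group = assign_age_group(ages),
                             roi = "R1", w = 0.9 - 0.004 * ages, I = 0.3)
  f <- suppressWarnings(fit_trends(tab_line, "R1", "w"))
  expect_equal(f$quadratic[3], 0, tolerance = 1e-10)
  expect_equal(f$linear[2], -0.004, tolerance = 1e-10)
  expect_identical(f$label, "linear-decline")

  # exact inverted parabola peaking at 45
  tab_par <- dplyr::mutate(tab_line, w = 0.8 - 2e-4 * (age - 45)^2)
  f2 <- suppressWarnings(fit_trends(tab_par, "R1", "w"))
  expect_lt(f2$quadratic[3], 0)
  expect_equal(-f2$quadratic[2] / (2 * f2$quadratic[3]), 45,
               tolerance = 1e-6)
  expect_identical(f2$label, "inverted-U")

  # random data against the closed-form normal equations
  withr::with_seed(6, y <- 0.5 - 0.002 * ages + rnorm(30, 0, 0.05))
  tab_r <- dplyr::mutate(tab_line, w = y)
  fr <- fit_trends(tab_r, "R1", "w")
  X1 <- cbind(1, ages)
  X2 <- cbind(1, ages, ages^2)
  expect_equal(fr$linear, as.double(solve(crossprod(X1), crossprod(X1, y))),
               tolerance = 1e-8)
  expect_equal(fr$quadratic, as.double(solve(crossprod(X2), crossprod(X2, y))),
               tolerance = 1e-8)
  # nested least squares: the quadratic can never fit worse
  expect_lte(fr$rss_quadratic, fr$rss_linear + 1e-12)
  expect_error(fit_trends(tab_line[1:3, ], "R1", "w"), "distinct ages")
})

test_that("trend classification follows its rules on constructed cases", {
  ages <- seq(4, 85, length.out = 40)
  base <- tibble::tibble(id = as.character(seq_along(ages)), age = ages,
                         group = assign_age_group(ages), roi = "R1", I = 0.3)
  # flat noise: no slope, no curvature
  flat <- dplyr::mutate(base, w = 0.5 + withr::with_seed(7, rnorm(40, 0, 0.03)))
  expect_identical(fit_trends(flat, "R1", "w")$label, "flat")
  # vertex outside the interior band is not a peak
  edgepar <- dplyr::mutate(base, w = 0.5 - 1e-4 * (age - 95)^2 +
                             withr::with_seed(8, rnorm(40, 0, 0.01)))
  expect_true(fit_trends(edgepar, "R1", "w")$label != "inverted-U")
  # a rising line is an incline
  up <- dplyr::mutate(base, w = 0.3 + 0.004 * age +
                        withr::with_seed(9, rnorm(40, 0, 0.02)))
  expect_identical(fit_trends(up, "R1", "w")$label, "linear-incline")
})

test_that("trend tables summarize every region", {
  tab <- toy_cohort_table(15, 15, n_roi = 4, seed = 10)
  tt <- trend_table(tab, "w")
  expect_identical(nrow(tt), 4L)
  expect_true(all(tt$rss_quadratic <= tt$rss_linear + 1e-12))
})

test_that("significant fractions format as printed percentages", {
  sf <- significant_fraction(3, 40)
  expect_equal(sf$percent, 7.5)
  expect_identical(sf$label, "7.5%")
  expect_error(significant_fraction(5, 4), "n_total")
})

test_that("the comparison report mirrors the publication layout", {
  tab <- toy_cohort_table(20, 20, n_roi = 6, delta_w = 0.2, affected = 1:2,
                          seed = 11)
  cmp <- compare_groups(tab, parameter = "w")
  rep <- report_comparison(cmp, significant_only = FALSE)
  expect_named(rep, c("roi", "parameter", "young", "old", "p_corrected"))
  expect_match(rep$young[1], "^\\d\\.\\d{2} \\(± \\d\\.\\d{2}\\)$")
})
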