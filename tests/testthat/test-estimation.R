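test_that("a forward-simulated target evaluates to perfect similarity", {
  sc <- tiny_sc(6)
  cfg <- quick_config(duration = 40, burn_in = 10)
  spec <- default_trend_spec(6)
  subj <- generate_subject(30, sc, spec, config = cfg, seed = 5,
                           measurement_noise_sd = 0)
  s <- evaluate_params(subj$true_params, sc, subj$empirical_fc, cfg,
                       seed = subj$sim_seed)
  expect_equal(s, 1, tolerance = 1e-12)
})

test_that("similarity varies across seeds within Monte-Carlo spread", {
  # evaluated in the strongly-coupled regime, where the parameter-driven
  # response dominates realization noise and similarity is a stable statistic
  sc <- tiny_sc(20, seed = 42)
  cfg <- sim_config(duration = 480, burn_in = 20, tr = 1)
  p <- baseline_params(20, G = 1.3)
  emp <- rmfm:::forward_fc(p, sc, cfg, 99, synaptic_constants(),
                           hemodynamic_constants())
  sims <- vapply(1:10, function(s) evaluate_params(p, sc, emp, cfg, seed = s),
                 numeric(1))
  expect_gt(length(unique(sims)), 1)
  expect_lt(sd(sims), 0.1)
})

test_that("degenerate targets are rejected", {
  sc0 <- validate_sc(matrix(0, 4, 4))
  p <- baseline_params(4)
  cfg <- quick_config(duration = 30, burn_in = 5)
  flat <- matrix(0.5, 4, 4); diag(flat) <- 1
  expect_error(evaluate_params(p, sc0, flat, cfg, seed = 1), "constant")
})

test_that("the default initialization grid enumerates 81 cells", {
  spec <- grid_spec()
  expect_identical(n_grid_cells(spec), 81L)
  expect_equal(spec$w_values, seq(0.1, 0.9, by = 0.1))
  expect_equal(spec$I_values, seq(0.1, 0.9, by = 0.1))
  expect_error(grid_spec(w_values = c(0.2, 0.1)), "increasing")
})

test_that("a degenerate 1x1 grid equals a single subject fit", {
  sc <- tiny_sc(5)
  cfg <- quick_config(duration = 30, burn_in = 5)
  emp <- generate_subject(40, sc, default_trend_spec(5), config = cfg,
                          seed = 2)$empirical_fc
  g <- init_grid(grid_spec(w_values = 0.5, I_values = 0.3), sc, emp,
                 config = cfg, base_seed = 17, n_iter = 1)
  expect_identical(nrow(g), 1L)
  # the documented per-cell seed rule: base_seed + 1000 * cell + replicate
  fit <- fit_subject(sc, emp,
                     init = baseline_params(5), n_iter = 1, config = cfg,
                     seed = 17 + 1000 + 1)
  expect_equal(g$similarity, max(fit$corr_trace), tolerance = 1e-12)
})

test_that("replicated grid cells average their seeded runs", {
  sc <- tiny_sc(5)
  cfg <- quick_config(duration = 30, burn_in = 5)
  emp <- generate_subject(40, sc, default_trend_spec(5), config = cfg,
                          seed = 2)$empirical_fc
  g <- init_grid(grid_spec(w_values = 0.4, I_values = 0.3, replicates = 3),
                 sc, emp, config = cfg, base_seed = 23, n_iter = 1)
  manual <- vapply(1:3, function(k) {
    f <- fit_subject(sc, emp, init = baseline_params(5, w = 0.4),
                     n_iter = 1, config = cfg, seed = 23 + 1000 + k)
    max(f$corr_trace)
  }, numeric(1))
  expect_equal(g$similarity, mean(manual), tolerance = 1e-12)
})

test_that("identical grid specs and seeds reproduce identical surfaces", {
  sc <- tiny_sc(4)
  cfg <- quick_config(duration = 20, burn_in = 5)
  emp <- generate_subject(40, sc, default_trend_spec(4), config = cfg,
                          seed = 3)$empirical_fc
  gs <- grid_spec(w_values = c(0.3, 0.6), I_values = 0.3)
  g1 <- init_grid(gs, sc, emp, config = cfg, base_seed = 5, n_iter = 1)
  g2 <- init_grid(gs, sc, emp, config = cfg, base_seed = 5, n_iter = 1)
  expect_identical(g1$similarity, g2$similarity)
})

test_that("grid refinement narrows around the best cells", {
  g <- tibble::tibble(
    w0 = rep(seq(0.1, 0.9, 0.1), each = 9),
    I0 = rep(seq(0.1, 0.9, 0.1), times = 9),
    similarity = 0, n_rep = 1L)
  g$similarity[abs(g$w0 - 0.3) < 1e-9 & abs(g$I0 - 0.4) < 1e-9] <- 0.9
  sp <- refine_grid(g, top_fraction = 1 / 81, finer_step = 0.05)
  expect_equal(range(sp$w_values), c(0.25, 0.35))
  expect_equal(range(sp$I_values), c(0.35, 0.45))

  # an all-equal surface carries no information: full range kept
  g2 <- g; g2$similarity <- 0.5
  sp2 <- refine_grid(g2, top_fraction = 0.1, finer_step = 0.1)
  expect_equal(range(sp2$w_values), c(0.1, 0.9))

  # bounding box of the top decile agrees with a sort-based oracle
  withr::with_seed(6, g3 <- dplyr::mutate(g, similarity = runif(81)))
  sp3 <- refine_grid(g3, top_fraction = 0.1, finer_step = 0.05)
  k <- ceiling(0.1 * 81)
  top <- g3[order(-g3$similarity)[seq_len(k)], ]
  expect_equal(min(sp3$w_values), max(0.1, min(top$w0) - 0.05))
  expect_equal(max(sp3$w_values), min(0.9, max(top$w0) + 0.05))
  expect_error(refine_grid(g[0, ]), "empty")
})

test_that("a one-iteration fit is the evaluated initialization", {
  sc <- tiny_sc(5)
  cfg <- quick_config(duration = 30, burn_in = 5)
  emp <- generate_subject(35, sc, default_trend_spec(5), config = cfg,
                          seed = 4)$empirical_fc
  init <- baseline_params(5)
  fit <- fit_subject(sc, emp, init, n_iter = 1, config = cfg, seed = 9)
  expect_length(fit$corr_trace, 1)
  expect_identical(fit$best_iter, 1L)
  expect_equal(fit$params$w, init$w)
  expect_equal(fit$corr_trace[1],
               evaluate_params(init, sc, emp, cfg,
                               seed = rmfm:::derive_seed(9, 1)),
               tolerance = 1e-12)
})

test_that("fits are deterministic and report the best-of-trace iterate", {
  sc <- tiny_sc(5)
  cfg <- quick_config(duration = 30, burn_in = 5)
  subj <- generate_subject(35, sc, default_trend_spec(5), config = cfg,
                           seed = 4, measurement_noise_sd = 0)
  init <- baseline_params(5)
  f1 <- fit_subject(sc, subj$empirical_fc, init, n_iter = 4, config = cfg,
                    seed = 31)
  f2 <- fit_subject(sc, subj$empirical_fc, init, n_iter = 4, config = cfg,
                    seed = 31)
  expect_identical(f1$corr_trace, f2$corr_trace)
  expect_identical(f1$params$w, f2$params$w)
  expect_equal(f1$corr_trace[f1$best_iter], max(f1$corr_trace))
  # starting at the truth, the best-of-trace contract guarantees no loss
  ft <- fit_subject(sc, subj$empirical_fc, subj$true_params, n_iter = 3,
                    config = cfg, seed = subj$sim_seed - 1)
  expect_gte(max(ft$corr_trace), ft$corr_trace[1])
})

test_that("a warm-started fit reproduces the cold fit exactly", {
  sc <- tiny_sc(4)
  cfg <- quick_config(duration = 30, burn_in = 5)
  emp <- generate_subject(50, sc, default_trend_spec(4), config = cfg,
                          seed = 6)$empirical_fc
  init <- baseline_params(4)
  cold <- fit_subject(sc, emp, init, n_iter = 3, config = cfg, seed = 13,
                      jacobian_every = Inf)
  warm <- precompute_jacobian(sc, init, config = cfg, seed = 13)
  hot <- fit_subject(sc, emp, init, n_iter = 3, config = cfg, seed = 13,
                     jacobian_every = Inf, warm_start = warm)
  expect_identical(cold$corr_trace, hot$corr_trace)
  expect_identical(cold$params$w, hot$params$w)
  expect_error(fit_subject(sc, emp, baseline_params(4, w = 0.6), n_iter = 2,
                           config = cfg, seed = 13, warm_start = warm),
               "different init")
})

test_that("a noiseless small system is refit to near-perfect similarity", {
  n <- 5
  sc <- tiny_sc(n, seed = 11)
  cfg <- sim_config(duration = 120, burn_in = 20, tr = 0.5)
  true <- withr::with_seed(7, regional_parameters(
    w = pmax(0.1, 0.5 + rnorm(n, 0, 0.15)),
    I = pmax(0.1, 0.3 + rnorm(n, 0, 0.015)), G = 1.3, sigma = 0.01))
  emp_seed <- 500
  fcobj <- rmfm:::forward_fc(true, sc, cfg, emp_seed,
                             synaptic_constants(), hemodynamic_constants())
  init <- regional_parameters(w = rep(0.5, n), I = rep(0.3, n), G = 1.3,
                              sigma = 0.01)
  fit <- fit_subject(sc, fcobj, init, n_iter = 20, config = cfg,
                     seed = emp_seed - 1, fd_step = 0.01,
                     prior_weight = 0.01)
  refit <- evaluate_params(fit$params, sc, fcobj, cfg, seed = emp_seed)
  expect_gte(refit, 0.95)
})

test_that("fit results serialize and parse losslessly", {
  sc <- tiny_sc(4)
  cfg <- quick_config(duration = 20, burn_in = 5)
  emp <- generate_subject(35, sc, default_trend_spec(4), config = cfg,
                          seed = 4)$empirical_fc
  fit <- fit_subject(sc, emp, baseline_params(4), n_iter = 2, config = cfg,
                     seed = 3)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_fit_result(fit, tmp, labels = sc$abbrevs)
  back <- read_fit_result(tmp)
  expect_equal(back$params$w, fit$params$w, tolerance = 1e-12)
  expect_equal(back$params$I, fit$params$I, tolerance = 1e-12)
  expect_equal(back$best_similarity, max(fit$corr_trace), tolerance = 1e-12)
  expect_identical(back$roi, sc$abbrevs)
})
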