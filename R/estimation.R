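#' Simulation configuration
#'
#' Bundles the forward-simulation settings shared by evaluation, grid search,
#' and fitting: integration step `dt` (default 10 ms for both the neural and
#' hemodynamic equations), total simulated `duration`, discarded `burn_in`,
#' BOLD sampling interval `tr`, initial gating `S0`, and hemodynamic
#' `substeps` per neural step.
#'
#' @param dt integration step, seconds.
#' @param duration total simulated time, seconds.
#' @param burn_in discarded initial interval, seconds.
#' @param tr BOLD sampling interval, seconds (integer multiple of `dt`).
#' @param S0 uniform initial gating.
#' @param substeps hemodynamic sub-steps per neural step.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.01, duration = 240, burn_in = 30, tr = 2,
                       S0 = 0.1, substeps = 1L) {
  check_scalar(dt, "dt", lower = 0, strict = TRUE)
  check_scalar(duration, "duration", lower = 0, strict = TRUE)
  check_scalar(burn_in, "burn_in", lower = 0)
  if (burn_in >= duration) abort("`duration` must exceed `burn_in`")
  structure(list(dt = dt, duration = duration, burn_in = burn_in, tr = tr,
                 S0 = S0, substeps = as.integer(substeps)),
            class = "sim_config")
}

# Forward model: parameters -> simulated FC. The hemodynamics are driven by
# the full gating trajectory and the burn-in is discarded from the BOLD
# output, so neural and hemodynamic transients are dropped together.
# Returns NULL when the simulated BOLD is degenerate (a constant series),
# which fitting treats as an unacceptable candidate.
forward_fc <- function(params, sc, config, seed, consts, hconsts) {
  traj <- simulate_neural(params, sc, duration = config$duration,
                          dt = config$dt, burn_in = 0,
                          seed = seed, S0 = config$S0, consts = consts)
  bold <- simulate_bold(traj, consts = hconsts, tr = config$tr,
                        substeps = config$substeps, burn_in = config$burn_in)
  tryCatch(compute_fc(bold), error = function(e) NULL)
}

#' Evaluate a parameter set against an empirical FC
#'
#' Runs the full forward model (neural dynamics, hemodynamics, FC) with the
#' given seed and returns the similarity (upper-triangle Pearson correlation)
#' between simulated and empirical FC. Deterministic given the seed.
#'
#' @param params a [regional_parameters()] object.
#' @param sc a [structural_connectome()].
#' @param empirical_fc an [fc_matrix()] (or bare correlation matrix).
#' @param config a [sim_config()].
#' @param seed integer seed for the neuronal noise.
#' @param consts,hconsts model constants.
#' @return Scalar similarity in `[-1, 1]`.
#' @export
evaluate_params <- function(params, sc, empirical_fc, config = sim_config(),
                            seed = 1, consts = synaptic_constants(),
                            hconsts = hemodynamic_constants()) {
  fc <- forward_fc(params, sc, config, seed, consts, hconsts)
  if (is.null(fc)) abort("simulated BOLD is degenerate (constant series)")
  fc_similarity(fc, empirical_fc)
}

#' Grid of initial parameter values
#'
#' The initialization grid for the sensitivity analysis: every combination of
#' a starting recurrent strength `w0` and starting subcortical input `I0`.
#' The default spans `[0.1, 0.9]` in steps of 0.1 on both axes — 81
#' initializations.
#'
#' @param w_values,I_values strictly increasing initial values.
#' @param replicates repeated seeded runs per cell; cell values are averaged.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(w_values = seq(0.1, 0.9, by = 0.1),
                      I_values = seq(0.1, 0.9, by = 0.1),
                      replicates = 1L) {
  for (v in list(w_values, I_values)) {
    if (!length(v) || is.unsorted(v, strictly = TRUE)) {
      abort("grid values must be non-empty and strictly increasing")
    }
  }
  if (replicates < 1) abort("`replicates` must be >= 1")
  structure(list(w_values = as.double(w_values),
                 I_values = as.double(I_values),
                 replicates = as.integer(replicates)),
            class = "grid_spec")
}

#' Number of initializations a grid enumerates
#' @param spec a [grid_spec()].
#' @return Integer count `length(w_values) * length(I_values)`.
#' @export
n_grid_cells <- function(spec) {
  length(spec$w_values) * length(spec$I_values)
}

#' Initial-parameter sensitivity grid
#'
#' For every `(w0, I0)` cell of the grid, initializes all regions uniformly
#' at `w_i = w0`, `I_i = I0`, runs [fit_subject()] at the configured
#' iteration budget, and records the best achieved similarity (averaged over
#' `spec$replicates` seeded repeats). The seed of cell `c` (1-based,
#' column-major over `w` then `I`) and replicate `k` is
#' `base_seed + 1000 * c + k`, making every cell independently reproducible.
#'
#' @param spec a [grid_spec()].
#' @param sc a [structural_connectome()].
#' @param empirical_fc target FC (typically a group average).
#' @param config a [sim_config()].
#' @param base_seed integer seed root.
#' @param n_iter fitting iterations per cell (default 500; reduce for quick
#'   surveys — initialization sensitivity is most visible at small budgets).
#' @param init_G,init_sigma global-parameter initialization for every cell.
#' @param ... passed to [fit_subject()].
#' @return A `grid_result`: tibble with columns `w0`, `I0`, `similarity`,
#'   `n_rep`, carrying the spec and run metadata as attributes.
#' @export
init_grid <- function(spec = grid_spec(), sc, empirical_fc,
                      config = sim_config(), base_seed = 1, n_iter = 500,
                      init_G = 0.5, init_sigma = 0.01, ...) {
  N <- n_regions(sc)
  cells <- tidyr::expand_grid(w0 = spec$w_values, I0 = spec$I_values)
  sims <- purrr::pmap_dbl(
    list(cells$w0, cells$I0, seq_len(nrow(cells))),
    function(w0, I0, idx) {
      vals <- vapply(seq_len(spec$replicates), function(k) {
        init <- regional_parameters(w = rep(w0, N), I = rep(I0, N),
                                    G = init_G, sigma = init_sigma)
        fit <- fit_subject(sc, empirical_fc, init = init, n_iter = n_iter,
                           config = config,
                           seed = derive_seed(base_seed, 1000 * idx + k), ...)
        max(fit$corr_trace, na.rm = TRUE)
      }, numeric(1))
      mean(vals)
    })
  out <- tibble::tibble(w0 = cells$w0, I0 = cells$I0, similarity = sims,
                        n_rep = spec$replicates)
  structure(out, spec = spec, base_seed = base_seed, n_iter = n_iter,
            class = c("grid_result", class(out)))
}

#' Refine an initialization grid around its best cells
#'
#' Returns a new [grid_spec()] covering the bounding box of the best
#' `top_fraction` of cells (ties at the cutoff value included), padded by
#' half the original cell width on each side, at `finer_step` spacing. When
#' every cell is equal there is no information to narrow on and the full
#' original range is returned.
#'
#' @param grid a [init_grid()] result.
#' @param top_fraction fraction of cells (by similarity) to cover.
#' @param finer_step new grid spacing.
#' @return A [grid_spec()] at the finer spacing.
#' @export
refine_grid <- function(grid, top_fraction = 0.1, finer_step = 0.05) {
  if (!nrow(grid)) abort("empty grid")
  sims <- grid$similarity
  if (diff(range(sims)) == 0) {
    top <- grid # no information to narrow on: keep the whole range
  } else {
    k <- max(1L, ceiling(top_fraction * nrow(grid) - 1e-9))
    cutoff <- sort(sims, decreasing = TRUE)[k]
    top <- grid[sims >= cutoff, , drop = FALSE]
  }
  pad <- function(vals, all_vals) {
    step <- if (length(unique(all_vals)) > 1) min(diff(sort(unique(all_vals)))) else finer_step
    c(max(min(all_vals), min(vals) - step / 2),
      min(max(all_vals), max(vals) + step / 2))
  }
  wr <- pad(top$w0, grid$w0)
  ir <- pad(top$I0, grid$I0)
  grid_spec(w_values = seq(wr[1], wr[2], by = finer_step),
            I_values = seq(ir[1], ir[2], by = finer_step),
            replicates = attr(grid, "spec")$replicates %||% 1L)
}

#' Fit regional parameters to an empirical FC
#'
#' Iterative estimation of `theta = (w_1..w_N, I_1..I_N, G, sigma)` by damped
#' Gauss-Newton on the upper-triangle FC residual. The whole fit runs under
#' common random numbers: every forward simulation reuses one fixed noise
#' seed derived from `seed`, so the objective is a deterministic function of
#' the parameters and finite-difference derivatives are not swamped by
#' sampling noise. Each iteration evaluates the forward model at the current
#' parameters, builds (or Broyden-updates) a finite-difference Jacobian of
#' the simulated FC vector with respect to `theta`, solves the damped normal
#' equations, and accepts the step only if the similarity improves, halving
#' it up to `max_halvings` times otherwise. Parameters are clipped to
#' `bounds` throughout. The returned parameters are the best-of-trace
#' iterate, never a later, worse one; exact ties keep the earliest
#' iteration.
#'
#' @param sc a [structural_connectome()].
#' @param empirical_fc target FC for this subject.
#' @param init a [regional_parameters()] initialization.
#' @param n_iter iteration budget (default 500).
#' @param config a [sim_config()].
#' @param seed integer seed; all simulations in the fit share the derived
#'   noise seed `seed + 1`.
#' @param fd_step absolute finite-difference step on each parameter.
#' @param lambda0 initial Levenberg damping factor.
#' @param bounds length-2 lower/upper clip bounds on every parameter.
#' @param max_halvings step halvings tried before raising the damping.
#' @param prior_weight precision of a Gaussian prior centred on the
#'   initialization, added to the least-squares objective as
#'   `sum(prior_weight * (theta - theta_init)^2)`; a scalar or a length
#'   `2N + 2` vector of per-parameter precisions (e.g. tighter on the
#'   subcortical inputs than on the recurrent strengths). The FC objective is nearly
#'   flat along directions that trade a region's recurrent strength against
#'   its subcortical input; the prior resolves that degeneracy toward the
#'   smallest parameter deviation, in the spirit of the Bayesian shrinkage
#'   used by expectation-maximization schemes for this model family. Set to
#'   0 for pure maximum-similarity fitting.
#' @param jacobian_every rebuild the finite-difference Jacobian every this
#'   many iterations (default 1 = every iteration; `Inf` = never rebuild);
#'   between rebuilds the previous Jacobian is carried forward with rank-one
#'   Broyden updates, trading some step quality for `2N + 2` fewer
#'   simulations per iteration.
#' @param warm_start optional [precompute_jacobian()] result for this exact
#'   `init`, `config`, and seed. Because the objective is a deterministic
#'   function of the parameters under common random numbers, subjects fitted
#'   from the same initialization on the same connectome share their first
#'   forward evaluation and Jacobian exactly; precomputing them once per
#'   cohort removes the dominant per-subject cost.
#' @param consts,hconsts model constants.
#' @return An object of class `fit_result`: `params` (best), `corr_trace`
#'   (per-iteration similarity), `best_iter`, `init`, `seed`, `n_iter`.
#' @export
fit_subject <- function(sc, empirical_fc, init, n_iter = 500,
                        config = sim_config(), seed = 1, fd_step = 0.015,
                        lambda0 = 1, bounds = c(1e-4, 10), max_halvings = 3,
                        prior_weight = 0.05, jacobian_every = 1L,
                        warm_start = NULL,
                        consts = synaptic_constants(),
                        hconsts = hemodynamic_constants()) {
  if (n_iter < 1) abort("`n_iter` must be >= 1")
  N <- n_regions(sc)
  emp <- if (inherits(empirical_fc, "fc_matrix")) empirical_fc$R else empirical_fc
  emp_vec <- upper_tri_vec(emp)
  if (sd(emp_vec) == 0) abort("empirical FC upper triangle is constant")

  theta <- clip(c(init$w, init$I, init$G, init$sigma), bounds[1], bounds[2])
  P <- length(theta)
  sim_seed <- derive_seed(seed, 1) # one noise realization for the whole fit
  unpack <- function(th) regional_parameters(w = th[1:N], I = th[(N + 1):(2 * N)],
                                             G = th[2 * N + 1], sigma = th[2 * N + 2])
  fwd <- function(th) {
    fc <- forward_fc(unpack(th), sc, config, sim_seed, consts, hconsts)
    if (is.null(fc)) NULL else upper_tri_vec(fc$R)
  }

  trace <- rep(NA_real_, n_iter)
  best_sim <- -Inf; best_theta <- theta; best_iter <- NA_integer_
  theta_prior <- theta
  pw <- rep(prior_weight, length.out = P)
  lambda <- lambda0
  J <- NULL
  if (!is.null(warm_start)) {
    if (!isTRUE(all.equal(warm_start$theta, theta)) ||
        warm_start$sim_seed != sim_seed) {
      abort("`warm_start` was computed for a different init or seed")
    }
    y0 <- warm_start$y0
    J <- warm_start$J
  } else {
    y0 <- fwd(theta)
  }

  for (it in seq_len(n_iter)) {
    sim <- if (is.null(y0) || sd(y0) == 0) NA_real_ else cor(y0, emp_vec)
    if (!is.finite(sim)) {
      warn(sprintf("similarity diverged at iteration %d; returning best-so-far", it))
      trace <- trace[seq_len(it - 1)]
      break
    }
    trace[it] <- sim
    if (sim > best_sim) {
      best_sim <- sim; best_theta <- theta; best_iter <- it
    }
    if (it == n_iter) break

    # Finite-difference Jacobian of the FC vector (common random numbers);
    # carried forward with Broyden updates between rebuilds.
    if (is.null(J) || (is.finite(jacobian_every) && it > 1 &&
                       (it - 1) %% jacobian_every == 0)) {
      J <- matrix(0, length(y0), P)
      for (k in seq_len(P)) {
        h <- fd_step
        thk <- theta
        if (thk[k] + h > bounds[2]) h <- -h
        thk[k] <- thk[k] + h
        yk <- fwd(thk)
        if (!is.null(yk)) J[, k] <- (yk - y0) / h
      }
    }
    resid <- emp_vec - y0
    obj0 <- sum(resid^2) + sum(pw * (theta - theta_prior)^2)
    JtJ <- crossprod(J)
    rhs <- crossprod(J, resid) + pw * (theta_prior - theta)
    delta <- tryCatch(
      solve(JtJ + diag(pw, P) + lambda * diag(diag(JtJ) + 1e-8), rhs),
      error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(delta)) {
      for (half in 0:max_halvings) {
        step <- as.double(delta) / 2^half
        cand <- clip(theta + step, bounds[1], bounds[2])
        y1 <- fwd(cand)
        s1 <- if (is.null(y1) || sd(y1) == 0) NA_real_ else cor(y1, emp_vec)
        obj1 <- if (is.null(y1)) Inf else {
          sum((emp_vec - y1)^2) + sum(pw * (cand - theta_prior)^2)
        }
        if (is.finite(s1) && obj1 < obj0) {
          dth <- cand - theta
          if (jacobian_every > 1L && sum(dth^2) > 0) {
            J <- J + ((y1 - y0 - J %*% dth) %*% t(dth)) / sum(dth^2)
          }
          theta <- cand
          y0 <- y1
          lambda <- max(lambda / 2, 1e-6)
          accepted <- TRUE
          break
        }
      }
    }
    if (!accepted) {
      lambda <- lambda * 4
      # a long rejection streak means the damped direction is exhausted;
      # restart the damping so fresh Jacobian information can act
      if (lambda > 1e4) lambda <- lambda0
    }
  }

  structure(list(params = unpack(best_theta), corr_trace = trace,
                 best_iter = best_iter, init = init, seed = seed,
                 n_iter = n_iter),
            class = "fit_result")
}

#' Precompute the shared first iteration of a cohort fit
#'
#' Evaluates the forward model and the finite-difference Jacobian at an
#' initialization, under the same common-random-numbers convention as
#' [fit_subject()]. Because every subject of a cohort is typically fitted
#' from the same initialization on a shared connectome, this work is
#' identical across subjects and can be done once.
#'
#' @inheritParams fit_subject
#' @return A list (`theta`, `y0`, `J`, `sim_seed`) accepted by
#'   `fit_subject(warm_start = )`.
#' @export
precompute_jacobian <- function(sc, init, config = sim_config(), seed = 1,
                                fd_step = 0.015, bounds = c(1e-4, 10),
                                consts = synaptic_constants(),
                                hconsts = hemodynamic_constants()) {
  N <- n_regions(sc)
  theta <- clip(c(init$w, init$I, init$G, init$sigma), bounds[1], bounds[2])
  P <- length(theta)
  sim_seed <- derive_seed(seed, 1)
  unpack <- function(th) regional_parameters(w = th[1:N], I = th[(N + 1):(2 * N)],
                                             G = th[2 * N + 1], sigma = th[2 * N + 2])
  fwd <- function(th) {
    fc <- forward_fc(unpack(th), sc, config, sim_seed, consts, hconsts)
    if (is.null(fc)) NULL else upper_tri_vec(fc$R)
  }
  y0 <- fwd(theta)
  if (is.null(y0)) abort("forward model is degenerate at the initialization")
  J <- matrix(0, length(y0), P)
  for (k in seq_len(P)) {
    h <- fd_step
    thk <- theta
    if (thk[k] + h > bounds[2]) h <- -h
    thk[k] <- thk[k] + h
    yk <- fwd(thk)
    if (!is.null(yk)) J[, k] <- (yk - y0) / h
  }
  list(theta = theta, y0 = y0, J = J, sim_seed = sim_seed)
}

#' Fit every subject of a synthetic cohort
#'
#' Convenience wrapper fitting each subject of a [generate_cohort()] result
#' from a common initialization. All subjects share one noise seed (common
#' random numbers across the cohort), so the simulator-realization component
#' of the fitting error is common mode and cancels in group contrasts; when
#' the cohort shares its connectome the first forward evaluation and
#' Jacobian are precomputed once ([precompute_jacobian()]).
#'
#' @param cohort a [generate_cohort()] tibble.
#' @param init common initialization; default all `w = 0.5`, `I = 0.3` with
#'   the cohort's global parameters.
#' @param n_iter per-subject iteration budget.
#' @param config a [sim_config()] (should match the cohort's).
#' @param seed shared fitting seed.
#' @param fd_step,lambda0,prior_weight,... passed to [fit_subject()].
#' @return Named list (by subject id) of `fit_result` objects.
#' @export
fit_cohort <- function(cohort, init = NULL, n_iter = 3,
                       config = sim_config(), seed = 1, fd_step = 0.03,
                       lambda0 = 10, prior_weight = 0.05, ...) {
  subs <- cohort$subject
  sc <- subs[[1]]$sc
  N <- n_regions(sc)
  init <- init %||% regional_parameters(
    w = rep(0.5, N), I = rep(0.3, N),
    G = subs[[1]]$true_params$G, sigma = subs[[1]]$true_params$sigma)
  shared <- all(vapply(subs, function(s) identical(s$sc$C, sc$C), logical(1)))
  warm <- if (shared) {
    precompute_jacobian(sc, init, config = config, seed = seed,
                        fd_step = fd_step)
  }
  fits <- lapply(subs, function(s) {
    fit_subject(s$sc, s$empirical_fc, init = init, n_iter = n_iter,
                config = config, seed = seed, fd_step = fd_step,
                lambda0 = lambda0, prior_weight = prior_weight,
                jacobian_every = Inf,
                warm_start = if (shared) warm, ...)
  })
  setNames(fits, cohort$id)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> N = %d regions, %d iterations, best similarity %.4f at iteration %d\n",
              length(x$params$w), length(x$corr_trace),
              max(x$corr_trace, na.rm = TRUE), x$best_iter))
  invisible(x)
}

#' Serialize a fit result to TSV
#'
#' Writes one row per region (`roi`, `w`, `I`) plus a small metadata header
#' of commented lines (seed, budget, best iteration and similarity, G,
#' sigma).
#'
#' @param fit a [fit_subject()] result.
#' @param path output file.
#' @param labels optional region labels.
#' @export
write_fit_result <- function(fit, path, labels = NULL) {
  N <- length(fit$params$w)
  meta <- c(
    sprintf("# seed\t%s", format(fit$seed)),
    sprintf("# n_iter\t%d", fit$n_iter),
    sprintf("# best_iter\t%d", fit$best_iter),
    sprintf("# best_similarity\t%.17g", max(fit$corr_trace, na.rm = TRUE)),
    sprintf("# G\t%.17g", fit$params$G),
    sprintf("# sigma\t%.17g", fit$params$sigma))
  body <- sprintf("%s\t%.17g\t%.17g", labels %||% paste0("R", seq_len(N)),
                  fit$params$w, fit$params$I)
  writeLines(c(meta, "roi\tw\tI", body), path)
  invisible(path)
}

#' Read a serialized fit result
#'
#' @param path file written by [write_fit_result()].
#' @return A list with `params` ([regional_parameters()]), `roi` labels,
#'   `best_similarity`, `best_iter`, `n_iter`, `seed`.
#' @export
read_fit_result <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- strsplit(sub("^# ", "", meta_lines), "\t")
  vals <- setNames(vapply(meta, `[`, character(1), 2),
                   vapply(meta, `[`, character(1), 1))
  df <- read.delim(text = paste(lines[!grepl("^# ", lines)], collapse = "\n"),
                   sep = "\t", stringsAsFactors = FALSE)
  list(params = regional_parameters(w = df$w, I = df$I,
                                    G = as.double(vals[["G"]]),
                                    sigma = as.double(vals[["sigma"]])),
       roi = df$roi,
       best_similarity = as.double(vals[["best_similarity"]]),
       best_iter = as.integer(vals[["best_iter"]]),
       n_iter = as.integer(vals[["n_iter"]]),
       seed = as.double(vals[["seed"]]))
}
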