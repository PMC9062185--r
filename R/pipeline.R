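# File-based pipeline commands: thin orchestration over the package's
# functions, reading and writing the delimited-text layouts. Each command is
# reproducible byte-for-byte given the same config and seed, and snapshots
# its effective configuration next to its outputs.

#' Generate and write a synthetic dataset
#'
#' @param config a [rmfm_config()].
#' @param out_dir output directory.
#' @param seed integer seed.
#' @return The output directory, invisibly.
#' @export
run_synth <- function(config = rmfm_config(), out_dir, seed = 1) {
  syn <- config$synthetic
  spec <- default_trend_spec(
    n_roi = syn$n_regions, n_decline = syn$n_decline,
    n_inverted_u = syn$n_inverted_u, w_baseline = syn$w_baseline,
    I_baseline = syn$I_baseline, decline_baseline = syn$decline_baseline,
    w_slope = syn$w_slope, peak_age = syn$peak_age,
    noise_sd = syn$noise_sd, I_noise_sd = syn$I_noise_sd)
  sampler <- if (identical(syn$age_distribution, "bimodal")) {
    age_sampler_bimodal()
  }
  cohort <- generate_cohort(
    n_subjects = syn$n_subjects, spec = spec, age_sampler = sampler,
    base_seed = seed,
    config = config_sim(config), n_regions = syn$n_regions,
    n_modules = syn$n_modules, density = syn$density,
    measurement_noise_sd = syn$measurement_noise_sd,
    G = syn$G, sigma = syn$sigma)
  write_dataset(cohort, out_dir)
  write_config(config, file.path(out_dir, "config.yaml"))
  run_log(out_dir, "synth: wrote %d subjects, %d regions to %s",
          nrow(cohort), syn$n_regions, out_dir)
  invisible(out_dir)
}

#' Forward-simulate BOLD and FC for one parameter set
#'
#' Reads a structural connectome and a regional-parameter table (TSV with
#' columns `roi`, `w`, `I`; `G` and `sigma` from the config), simulates the
#' BOLD time series, and writes both the BOLD TSV and the FC matrix.
#'
#' @param config a [rmfm_config()].
#' @param sc_path delimited SC matrix file.
#' @param params_path parameter TSV (`roi`, `w`, `I`).
#' @param out_prefix output path prefix; writes `<prefix>_bold.tsv` and
#'   `<prefix>_fc.txt`.
#' @param seed integer seed.
#' @return Named vector of the two output paths, invisibly.
#' @export
run_simulate <- function(config = rmfm_config(), sc_path, params_path,
                         out_prefix, seed = 1) {
  sc <- validate_sc(read_matrix(sc_path))
  pdf <- read.delim(params_path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("w", "I") %in% names(pdf))) {
    abort(sprintf("parameter table %s needs columns `w` and `I`", params_path))
  }
  params <- regional_parameters(w = pdf$w, I = pdf$I,
                                G = config$synthetic$G,
                                sigma = config$synthetic$sigma)
  cfg <- config_sim(config)
  traj <- simulate_neural(params, sc, duration = cfg$duration, dt = cfg$dt,
                          burn_in = cfg$burn_in, seed = seed, S0 = cfg$S0)
  bold <- simulate_bold(traj, tr = cfg$tr, substeps = cfg$substeps)
  fc <- compute_fc(bold, labels = sc$abbrevs)
  bold_path <- paste0(out_prefix, "_bold.tsv")
  fc_path <- paste0(out_prefix, "_fc.txt")
  write_bold(bold, bold_path, labels = sc$abbrevs)
  write_matrix(fc$R, fc_path)
  invisible(c(bold = bold_path, fc = fc_path))
}

#' Run the initialization-sensitivity grid
#'
#' @param config a [rmfm_config()]; the `grid` block sets the ranges, step,
#'   and replicates, the `fitting` block the per-cell iteration budget.
#' @param sc_path,fc_path delimited SC and target-FC matrix files.
#' @param out_path output TSV (one row per cell).
#' @param seed integer seed.
#' @param n_iter per-cell fitting budget; defaults to the config value.
#' @return The [init_grid()] result, invisibly.
#' @export
run_grid <- function(config = rmfm_config(), sc_path, fc_path, out_path,
                     seed = 1, n_iter = NULL) {
  g <- config$grid
  spec <- grid_spec(w_values = seq(g$w_min, g$w_max, by = g$step),
                    I_values = seq(g$I_min, g$I_max, by = g$step),
                    replicates = g$replicates)
  sc <- validate_sc(read_matrix(sc_path))
  fc <- fc_matrix(read_matrix(fc_path, expected_n = nrow(sc$C)))
  grid <- init_grid(spec, sc, fc, config = config_sim(config),
                    base_seed = seed,
                    n_iter = n_iter %||% config$fitting$n_iter,
                    init_G = config$fitting$init_G,
                    init_sigma = config$fitting$init_sigma)
  write.table(tibble::as_tibble(grid), out_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(grid)
}

#' Fit every subject of a dataset
#'
#' Iterates the subject table, fitting each subject's parameters to their
#' empirical FC and writing one result file per subject
#' (`<out_dir>/<id>_fit.tsv`). Completed subjects are skipped on rerun, so
#' an interrupted run resumes where it stopped. Malformed subject rows are
#' skipped with a logged warning; their ids are returned in the
#' `"skipped"` attribute.
#'
#' @param config a [rmfm_config()].
#' @param dataset_dir dataset directory ([write_dataset()] layout).
#' @param out_dir output directory for fit files.
#' @param seed integer fitting seed, shared by every subject: under common
#'   random numbers the simulator-realization component of the fitting
#'   error is then common to the whole cohort and cancels in group
#'   contrasts. When all subjects share one connectome the first forward
#'   evaluation and Jacobian are precomputed once.
#' @param n_iter per-subject budget; defaults to the config value.
#' @return Tibble with one row per fitted subject (`id`, `best_similarity`,
#'   `best_iter`), invisibly.
#' @export
run_fit <- function(config = rmfm_config(), dataset_dir, out_dir, seed = 1,
                    n_iter = NULL) {
  ds <- read_dataset(dataset_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(out_dir, "config.yaml"))
  n_iter <- n_iter %||% config$fitting$n_iter
  fit_cfg <- config$fitting
  cfg <- config_sim(config)
  make_init <- function(N) {
    regional_parameters(w = rep(fit_cfg$init_w, N),
                        I = rep(fit_cfg$init_I, N),
                        G = fit_cfg$init_G, sigma = fit_cfg$init_sigma)
  }
  shared_sc <- length(unique(ds$subjects$sc_path)) == 1L ||
    identical(ds$read_sc(ds$subjects$id[1])$C,
              ds$read_sc(ds$subjects$id[nrow(ds$subjects)])$C)
  warm <- NULL
  skipped <- character(0)
  rows <- list()
  for (i in seq_len(nrow(ds$subjects))) {
    id <- as.character(ds$subjects$id[i])
    out_path <- file.path(out_dir, paste0(id, "_fit.tsv"))
    if (file.exists(out_path)) {
      run_log(out_dir, "fit: %s already complete, skipping", id)
      prev <- read_fit_result(out_path)
      rows[[id]] <- tibble::tibble(id = id,
                                   best_similarity = prev$best_similarity,
                                   best_iter = prev$best_iter)
      next
    }
    res <- tryCatch({
      sc <- ds$read_sc(id)
      fc <- ds$read_fc(id)
      N <- nrow(sc$C)
      init <- make_init(N)
      if (shared_sc && is.null(warm)) {
        warm <- precompute_jacobian(sc, init, config = cfg, seed = seed,
                                    fd_step = fit_cfg$fd_step,
                                    bounds = fit_cfg$bounds)
      }
      fit <- fit_subject(sc, fc, init = init, n_iter = n_iter, config = cfg,
                         seed = seed,
                         fd_step = fit_cfg$fd_step,
                         lambda0 = fit_cfg$lambda0,
                         prior_weight = fit_cfg$prior_weight,
                         jacobian_every = fit_cfg$jacobian_every,
                         bounds = fit_cfg$bounds,
                         max_halvings = fit_cfg$max_halvings,
                         warm_start = if (shared_sc) warm)
      write_fit_result(fit, out_path, labels = ds$roi$abbrev)
      best <- max(fit$corr_trace, na.rm = TRUE)
      run_log(out_dir, "fit: %s best similarity %.4f (iteration %d/%d)",
              id, best, fit$best_iter, n_iter)
      tibble::tibble(id = id, best_similarity = best,
                     best_iter = fit$best_iter)
    }, error = function(e) {
      run_log(out_dir, "fit: skipping %s (%s)", id, conditionMessage(e))
      NULL
    })
    if (is.null(res)) skipped <- c(skipped, id) else rows[[id]] <- res
  }
  out <- dplyr::bind_rows(rows)
  if (length(skipped)) {
    warn(sprintf("skipped %d subject(s): %s", length(skipped),
                 paste(skipped, collapse = ", ")))
  }
  attr(out, "skipped") <- skipped
  invisible(out)
}

#' Cohort-level group comparison and age-trend analysis
#'
#' Builds the cohort table from per-subject fit files and the subject
#' table, runs the young-vs-old comparison for both parameters, fits first-
#' and second-order age polynomials per region, and writes the
#' publication-style comparison report and the trend tables as TSV.
#'
#' @param config a [rmfm_config()].
#' @param fits_dir directory of [run_fit()] outputs.
#' @param subjects_path subject table TSV.
#' @param out_dir output directory.
#' @return List with `comparison`, `trends_w`, `trends_I`, invisibly.
#' @export
run_analyze <- function(config = rmfm_config(), fits_dir, subjects_path,
                        out_dir) {
  subjects <- read_subject_table(subjects_path)
  paths <- file.path(fits_dir, paste0(subjects$id, "_fit.tsv"))
  missing <- subjects$id[!file.exists(paths)]
  if (length(missing)) {
    abort(sprintf("missing fit files for subject(s): %s",
                  paste(missing, collapse = ", ")))
  }
  fits <- setNames(lapply(paths, read_fit_result), as.character(subjects$id))
  roi <- fits[[1]]$roi
  cohort <- build_cohort_table(fits, subjects, roi = roi)
  st <- config$statistics
  comparison <- compare_groups(cohort, parameter = c("w", "I"),
                               alpha = st$alpha, var_equal = st$var_equal,
                               fdr_family = st$fdr_family)
  trends_w <- trend_table(cohort, "w")
  trends_I <- trend_table(cohort, "I")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(out_dir, "config.yaml"))
  write.table(tibble::as_tibble(comparison),
              file.path(out_dir, "group_comparison.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report_comparison(comparison),
              file.path(out_dir, "comparison_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(trends_w, file.path(out_dir, "trends_w.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(trends_I, file.path(out_dir, "trends_I.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  n_sig <- sum(comparison$significant[comparison$parameter == "w"])
  frac <- significant_fraction(n_sig, length(roi))
  run_log(out_dir, "analyze: %d of %d regions significant in w (%s)",
          n_sig, length(roi), frac$label)
  invisible(list(comparison = comparison, trends_w = trends_w,
                 trends_I = trends_I))
}
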