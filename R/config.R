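#' Pipeline run configuration
#'
#' Nested configuration for the file-based pipeline commands, with every
#' default equal to the reference analysis settings where one exists:
#' 500 fitting iterations, an initialization grid over `[0.1, 0.9]` in steps
#' of 0.1, and significance level 0.05 on FDR-corrected p-values. Settings
#' the reference analysis leaves open (integration step, scan duration, TR,
#' connectome dimensions) carry the package's declared defaults.
#'
#' @param overrides a nested list (or path to a YAML file) of settings to
#'   override.
#' @return A `rmfm_config` nested list.
#' @export
rmfm_config <- function(overrides = NULL) {
  defaults <- list(
    simulation = list(dt = 0.01, duration = 240, burn_in = 30, tr = 2,
                      S0 = 0.1, substeps = 1L),
    fitting = list(n_iter = 500L, fd_step = 0.03, lambda0 = 10,
                   prior_weight = 0.05, jacobian_every = Inf,
                   bounds = c(1e-4, 10), max_halvings = 3L,
                   init_w = 0.5, init_I = 0.3, init_G = 0.5,
                   init_sigma = 0.01),
    grid = list(w_min = 0.1, w_max = 0.9, I_min = 0.1, I_max = 0.9,
                step = 0.1, replicates = 1L, refine_top_fraction = 0.1,
                refine_step = 0.05),
    statistics = list(alpha = 0.05, fdr_family = "per_parameter",
                      var_equal = FALSE),
    synthetic = list(n_regions = 20L, n_modules = 2L, density = 0.6,
                     n_subjects = 40L, age_distribution = "uniform",
                     n_decline = 3L, n_inverted_u = 0L,
                     w_baseline = 0.5, I_baseline = 0.3,
                     decline_baseline = 0.6, w_slope = -0.0075,
                     peak_age = 45, noise_sd = 0.05, I_noise_sd = 0.03,
                     measurement_noise_sd = 0.02, G = 0.5, sigma = 0.01))
  if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
  cfg <- if (is.null(overrides)) defaults else merge_config(defaults, overrides)
  structure(cfg, class = "rmfm_config")
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Write the effective configuration to YAML
#'
#' Every pipeline command snapshots its effective configuration into its
#' output directory for provenance; the written file parses back to the
#' same configuration.
#'
#' @param config a [rmfm_config()].
#' @param path output YAML file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_sim <- function(config) {
  s <- config$simulation
  sim_config(dt = s$dt, duration = s$duration, burn_in = s$burn_in,
             tr = s$tr, S0 = s$S0, substeps = s$substeps)
}

run_log <- function(dir, ...) {
  msg <- sprintf(...)
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  cat(line, "\n", sep = "")
  if (!is.null(dir)) cat(line, "\n", sep = "", file = file.path(dir, "run.log"),
                         append = TRUE)
  invisible(msg)
}
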