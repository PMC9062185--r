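#' Ground-truth age-trend specification
#'
#' Describes, for every region and parameter, the true age trajectory the
#' synthetic cohort follows: `"linear-decline"` (or incline, via the slope
#' sign), `"inverted-U"`, or `"flat"`. For linear trends `baseline` is the
#' value at age 45 and `slope` is per year; for inverted-U trends `baseline`
#' is the peak value reached at `peak_age` and `curvature` is the (positive)
#' quadratic fall-off per squared year. `noise_sd` is the between-subject
#' standard deviation around the trajectory.
#'
#' @param roi region labels.
#' @param parameter `"w"` or `"I"` per row.
#' @param kind trend kind per row.
#' @param baseline,slope,peak_age,curvature,noise_sd trajectory parameters
#'   (recycled).
#' @return A `trend_spec` tibble with one row per region x parameter.
#' @export
trend_spec <- function(roi, parameter, kind, baseline, slope = 0,
                       peak_age = 45, curvature = 0, noise_sd = 0.05) {
  kind <- match.arg(kind, c("linear-decline", "linear-incline", "inverted-U",
                            "flat"), several.ok = TRUE)
  out <- tibble::tibble(roi = roi, parameter = parameter, kind = kind,
                        baseline = baseline, slope = slope,
                        peak_age = peak_age, curvature = curvature,
                        noise_sd = noise_sd)
  if (any(out$noise_sd < 0)) abort("`noise_sd` must be >= 0")
  structure(out, class = c("trend_spec", class(out)))
}

#' Default cohort ground truth
#'
#' A convenience builder: all regions flat at the given baselines except the
#' first `n_decline` regions of `w`, which decline linearly, and the next
#' `n_inverted_u`, which follow an inverted U peaking at `peak_age`.
#' Age-affected regions sit at `decline_baseline` in mid-life and lose about
#' 0.45 of recurrent strength between a 10-year-old and a 70-year-old — the
#' separation scale reported for the most strongly aging frontal-pole
#' regions in lifespan cohorts. Subcortical input varies less between
#' subjects than recurrent strength (`I_noise_sd < noise_sd`), matching the
#' observation that group contrasts in `I` are weak.
#'
#' @param n_roi number of regions.
#' @param n_decline regions with linearly declining `w`.
#' @param n_inverted_u regions with inverted-U `w`.
#' @param w_baseline,I_baseline trajectory levels at age 45 for unaffected
#'   regions.
#' @param decline_baseline mid-life level of the age-affected regions.
#' @param w_slope decline rate per year for the declining regions.
#' @param peak_age,w_curvature inverted-U shape parameters.
#' @param noise_sd between-subject noise on `w`.
#' @param I_noise_sd between-subject noise on `I`.
#' @return A `trend_spec` tibble.
#' @export
default_trend_spec <- function(n_roi, n_decline = 0, n_inverted_u = 0,
                               w_baseline = 0.5, I_baseline = 0.3,
                               decline_baseline = 0.6, w_slope = -0.0075,
                               peak_age = 45, w_curvature = 1.25e-4,
                               noise_sd = 0.05, I_noise_sd = 0.03) {
  if (n_decline + n_inverted_u > n_roi) abort("more trend regions than regions")
  roi <- paste0("R", seq_len(n_roi))
  kind <- rep("flat", n_roi)
  slope <- rep(0, n_roi)
  curv <- rep(0, n_roi)
  base <- rep(w_baseline, n_roi)
  if (n_decline > 0) {
    kind[seq_len(n_decline)] <- "linear-decline"
    slope[seq_len(n_decline)] <- w_slope
    base[seq_len(n_decline)] <- decline_baseline
  }
  if (n_inverted_u > 0) {
    idx <- n_decline + seq_len(n_inverted_u)
    kind[idx] <- "inverted-U"
    curv[idx] <- w_curvature
    base[idx] <- decline_baseline
  }
  dplyr::bind_rows(
    trend_spec(roi, "w", kind, baseline = base, slope = slope,
               peak_age = peak_age, curvature = curv, noise_sd = noise_sd),
    trend_spec(roi, "I", "flat", baseline = I_baseline,
               noise_sd = I_noise_sd))
}

# Deterministic trajectory value (no subject noise).
trend_value_at <- function(spec_rows, age) {
  v <- numeric(nrow(spec_rows))
  for (i in seq_len(nrow(spec_rows))) {
    r <- spec_rows[i, ]
    v[i] <- switch(r$kind,
      "linear-decline" = ,
      "linear-incline" = r$baseline + r$slope * (age - 45),
      "inverted-U" = r$baseline - r$curvature * (age - r$peak_age)^2,
      "flat" = r$baseline)
  }
  v
}

#' Ground-truth parameters for a subject of a given age
#'
#' Evaluates the trend curves at `age`, adds subject-level Gaussian noise
#' with the per-region `noise_sd`, and clips to `(0, 2]`.
#'
#' @param age subject age in years.
#' @param spec a [trend_spec()] tibble covering both parameters.
#' @param subject_seed seed for the subject-level noise.
#' @param G,sigma global parameters (fixed across the cohort).
#' @return A [regional_parameters()] object.
#' @export
true_params_for_age <- function(age, spec, subject_seed = 1, G = 0.5,
                                sigma = 0.01) {
  sw <- spec[spec$parameter == "w", , drop = FALSE]
  si <- spec[spec$parameter == "I", , drop = FALSE]
  if (!nrow(sw) || !nrow(si)) abort("`spec` must cover both `w` and `I`")
  w0 <- trend_value_at(sw, age)
  I0 <- trend_value_at(si, age)
  with_seed(subject_seed, {
    w0 <- w0 + rnorm(nrow(sw), 0, sw$noise_sd)
    I0 <- I0 + rnorm(nrow(si), 0, si$noise_sd)
  })
  regional_parameters(w = clip(w0, 1e-3, 2), I = clip(I0, 1e-3, 2),
                      G = G, sigma = sigma)
}

#' Generate a synthetic structural connectome
#'
#' A modular weighted graph: regions are assigned round-robin to
#' `n_modules` modules, within-module edges appear with higher probability
#' than between-module edges (1.5x and 0.5x the target `density`,
#' respectively, capped at 1), and edge weights are log-normal. The result
#' is symmetric, nonnegative, zero-diagonal, and normalized so the maximum
#' entry equals `weight_scale`.
#'
#' @param n_regions number of regions (>= 2).
#' @param n_modules number of modules.
#' @param density target edge density in `(0, 1]`.
#' @param weight_scale maximum edge weight after normalization.
#' @param seed integer seed.
#' @return A [structural_connectome()].
#' @export
generate_sc <- function(n_regions, n_modules = 2, density = 0.6,
                        weight_scale = 1, seed = 1) {
  if (n_regions < 2) abort("`n_regions` must be >= 2")
  if (density <= 0 || density > 1) abort("`density` must be in (0, 1]")
  module <- rep(seq_len(n_modules), length.out = n_regions)
  p_within <- min(1, 1.5 * density)
  p_between <- min(1, 0.5 * density)
  C <- matrix(0, n_regions, n_regions)
  with_seed(seed, {
    for (i in seq_len(n_regions - 1)) {
      for (j in (i + 1):n_regions) {
        p <- if (module[i] == module[j]) p_within else p_between
        if (runif(1) < p) {
          wgt <- exp(rnorm(1, mean = -0.5, sd = 0.45))
          if (module[i] == module[j]) wgt <- wgt * 1.5
          C[i, j] <- C[j, i] <- wgt
        }
      }
    }
  })
  if (max(C) > 0) C <- C * (weight_scale / max(C))
  validate_sc(C)
}

#' Generate one synthetic subject
#'
#' Draws ground-truth regional parameters for the subject's age, runs the
#' full forward model (neural dynamics, hemodynamics, FC), and optionally
#' corrupts the FC with measurement noise: the upper-triangle entries are
#' jittered with Gaussian noise, the matrix re-symmetrized, clipped to
#' `[-1, 1]`, and the unit diagonal restored. The simulation seed is stored
#' as `sim_seed` so the noiseless subject can be reproduced exactly.
#'
#' @param age subject age in years.
#' @param sc shared [structural_connectome()].
#' @param spec a [trend_spec()].
#' @param config a [sim_config()].
#' @param seed subject seed; parameter noise, simulation, and measurement
#'   noise use fixed offsets of it.
#' @param measurement_noise_sd FC measurement noise (0 disables).
#' @param G,sigma global parameters.
#' @param id subject identifier.
#' @return An object of class `synthetic_subject`: list with `id`, `age`,
#'   `sex`, `sc`, `true_params`, `empirical_fc`, `seed`, `sim_seed`.
#' @export
generate_subject <- function(age, sc, spec, config = sim_config(), seed = 1,
                             measurement_noise_sd = 0.02, G = 0.5,
                             sigma = 0.01, id = "S1") {
  true_params <- true_params_for_age(age, spec, subject_seed = seed,
                                     G = G, sigma = sigma)
  sim_seed <- derive_seed(seed, 1000003)
  fc <- forward_fc(true_params, sc, config, sim_seed,
                   synaptic_constants(), hemodynamic_constants())
  if (is.null(fc)) abort("forward simulation produced a degenerate FC")
  R <- fc$R
  if (measurement_noise_sd > 0) {
    with_seed(derive_seed(seed, 2000003), {
      ut <- upper.tri(R)
      R[ut] <- R[ut] + rnorm(sum(ut), 0, measurement_noise_sd)
    })
    R[lower.tri(R)] <- t(R)[lower.tri(R)]
    R <- clip(R, -1, 1)
    diag(R) <- 1
  }
  structure(list(id = id, age = age, sex = NA_character_, sc = sc,
                 true_params = true_params,
                 empirical_fc = fc_matrix(R, labels = sc$abbrevs),
                 seed = seed, sim_seed = sim_seed),
            class = "synthetic_subject")
}

#' Bimodal young/old age sampler
#'
#' Returns a sampler drawing `n` ages split between a young band (4-19 y)
#' and an old band (61-85 y), for group-comparison experiments.
#'
#' @param prop_young fraction of subjects in the young band.
#' @return A function of `n` returning ages.
#' @export
age_sampler_bimodal <- function(prop_young = 0.5) {
  function(n) {
    n_young <- round(prop_young * n)
    c(runif(n_young, 4, 19), runif(n - n_young, 61, 85))
  }
}

#' Generate a synthetic cohort
#'
#' Ages are drawn from `age_sampler` (default uniform over 4-85 years, the
#' span of a lifespan sample), sexes at random, one structural connectome is
#' shared by the whole cohort (or perturbed per subject), and each subject's
#' "empirical" FC is produced by the package's own forward model plus
#' measurement noise. Fully deterministic given `base_seed`.
#'
#' @param n_subjects cohort size.
#' @param spec a [trend_spec()]; default [default_trend_spec()] for
#'   `n_regions` flat regions.
#' @param age_sampler function of `n` returning ages; default uniform 4-85.
#' @param shared_sc share one connectome (default) or redraw edge weights
#'   per subject.
#' @param base_seed integer seed root.
#' @param config a [sim_config()].
#' @param n_regions,n_modules,density connectome dimensions (used when `sc`
#'   not supplied).
#' @param sc optional pre-built connectome.
#' @param ... passed to [generate_subject()].
#' @return A `synthetic_cohort` tibble: columns `id`, `age`, `sex`, `seed`,
#'   and list-columns `subject` (the full [generate_subject()] objects).
#' @export
generate_cohort <- function(n_subjects, spec = NULL, age_sampler = NULL,
                            shared_sc = TRUE, base_seed = 1,
                            config = sim_config(), n_regions = 20,
                            n_modules = 2, density = 0.6, sc = NULL, ...) {
  if (n_subjects < 1) abort("`n_subjects` must be >= 1")
  spec <- spec %||% default_trend_spec(n_regions)
  n_regions <- sum(spec$parameter == "w")
  sampler <- age_sampler %||% function(n) runif(n, 4, 85)
  ages <- with_seed(derive_seed(base_seed, 11), sampler(n_subjects))
  sexes <- with_seed(derive_seed(base_seed, 13),
                     sample(c("M", "F"), n_subjects, replace = TRUE))
  if (is.null(sc)) {
    sc <- generate_sc(n_regions, n_modules = n_modules, density = density,
                      seed = derive_seed(base_seed, 17))
  }
  subjects <- purrr::map(seq_len(n_subjects), function(i) {
    sc_i <- if (shared_sc) sc else generate_sc(
      n_regions, n_modules = n_modules, density = density,
      seed = derive_seed(base_seed, 17 + i))
    s <- generate_subject(ages[i], sc_i, spec, config = config,
                          seed = derive_seed(base_seed, 100000 + 1000 * i),
                          id = sprintf("S%03d", i), ...)
    s$sex <- sexes[i]
    s
  })
  out <- tibble::tibble(
    id = vapply(subjects, `[[`, character(1), "id"),
    age = ages, sex = sexes,
    seed = vapply(subjects, `[[`, numeric(1), "seed"),
    subject = subjects)
  structure(out, spec = spec, base_seed = base_seed,
            class = c("synthetic_cohort", class(out)))
}

#' Materialize a synthetic cohort as an on-disk dataset
#'
#' Writes the layout the file-based pipeline reads back: a subject table
#' (`subjects.tsv` with `id`, `age`, `sex`, `sc_path`, `fc_path`), an ROI
#' table (`roi.tsv`), and per-subject SC and FC matrices as delimited text.
#' The pipeline cannot distinguish this synthetic dataset from a real one.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "sc"), showWarnings = FALSE)
  dir.create(file.path(dir, "fc"), showWarnings = FALSE)
  subs <- cohort$subject
  sc_paths <- file.path("sc", paste0(cohort$id, ".txt"))
  fc_paths <- file.path("fc", paste0(cohort$id, ".txt"))
  for (i in seq_along(subs)) {
    write_matrix(subs[[i]]$sc$C, file.path(dir, sc_paths[i]))
    write_matrix(subs[[i]]$empirical_fc$R, file.path(dir, fc_paths[i]))
  }
  sc1 <- subs[[1]]$sc
  roi <- tibble::tibble(index = seq_along(sc1$labels), name = sc1$labels,
                        abbrev = sc1$abbrevs)
  write_roi_table(roi, file.path(dir, "roi.tsv"))
  write_subject_table(
    tibble::tibble(id = cohort$id, age = cohort$age, sex = cohort$sex,
                   sc_path = sc_paths, fc_path = fc_paths),
    file.path(dir, "subjects.tsv"))
  # ground truth, for validation only (the pipeline never reads it)
  truth <- purrr::map_dfr(subs, function(s) {
    tibble::tibble(id = s$id, roi = s$sc$abbrevs,
                   true_w = s$true_params$w, true_I = s$true_params$I)
  })
  write.table(truth, file.path(dir, "ground_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a dataset directory
#'
#' @param dir directory written by [write_dataset()] (or following the same
#'   layout).
#' @return A list with `subjects` (tibble), `roi` (tibble), and functions of
#'   a subject id `read_sc(id)`, `read_fc(id)` loading the matrices.
#' @export
read_dataset <- function(dir) {
  subjects <- read_subject_table(file.path(dir, "subjects.tsv"))
  roi <- read_roi_table(file.path(dir, "roi.tsv"))
  n <- nrow(roi)
  list(
    subjects = subjects,
    roi = roi,
    read_sc = function(id) {
      p <- subjects$sc_path[match(id, subjects$id)]
      validate_sc(read_matrix(file.path(dir, p), expected_n = n),
                  labels = roi$name, abbrevs = roi$abbrev)
    },
    read_fc = function(id) {
      p <- subjects$fc_path[match(id, subjects$id)]
      fc_matrix(read_matrix(file.path(dir, p), expected_n = n),
                labels = roi$abbrev)
    })
}
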