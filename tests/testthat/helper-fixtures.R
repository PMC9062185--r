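# Shared fixtures: every object is built in code, seeded, and small enough
# for fast runs. Simulation settings here are deliberately short; the
# package defaults describe full analyses.

quick_config <- function(duration = 60, burn_in = 10, tr = 0.5) {
  sim_config(duration = duration, burn_in = burn_in, tr = tr)
}

tiny_sc <- function(n = 6, seed = 42) generate_sc(n, seed = seed)

baseline_params <- function(n, w = 0.5, I = 0.3, G = 0.5, sigma = 0.01) {
  regional_parameters(w = rep(w, n), I = rep(I, n), G = G, sigma = sigma)
}

# A small deterministic correlation-like matrix for FC plumbing tests.
toy_fc <- function(n = 5, seed = 1) {
  Y <- withr::with_seed(seed, matrix(rnorm(40 * n), 40, n))
  compute_fc(Y)
}

# Long cohort-style table of parameter draws without any simulation.
toy_cohort_table <- function(n_young = 20, n_old = 20, n_roi = 10,
                             delta_w = 0, affected = integer(0), sd = 0.05,
                             seed = 1) {
  withr::with_seed(seed, {
    ages <- c(runif(n_young, 5, 18), runif(n_old, 62, 84))
    purrr::map_dfr(seq_along(ages), function(i) {
      mu <- rep(0.5, n_roi)
      if (ages[i] > 60) mu[affected] <- mu[affected] - delta_w
      tibble::tibble(
        id = sprintf("S%03d", i), age = ages[i], sex = "F",
        group = assign_age_group(ages[i]),
        roi = paste0("R", seq_len(n_roi)),
        w = rnorm(n_roi, mu, sd), I = rnorm(n_roi, 0.3, sd))
    })
  })
}
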