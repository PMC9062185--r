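#' Resting hemodynamic state
#'
#' The Balloon-Windkessel state at rest in normalized units: vasodilatory
#' signal `z = 0`, inflow `f = 1`, blood volume `v = 1`, deoxyhemoglobin
#' content `q = 1`.
#'
#' @param n number of regions.
#' @return An object of class `hemodynamic_state`.
#' @export
hemodynamic_state <- function(n) {
  structure(list(z = rep(0, n), f = rep(1, n), v = rep(1, n), q = rep(1, n)),
            class = "hemodynamic_state")
}

#' Balloon-Windkessel state derivatives
#'
#' Right-hand side of the hemodynamic ODEs driven by gating activity `S`:
#' \deqn{\dot z = S - \kappa z - \gamma (f - 1), \quad \dot f = z,}
#' \deqn{\tau \dot v = f - v^{1/\alpha}, \quad
#'       \tau \dot q = \frac{f}{\rho}\left[1 - (1-\rho)^{1/f}\right]
#'                     - q\, v^{1/\alpha - 1}.}
#'
#' @param state a [hemodynamic_state()] with strictly positive `f`, `v`, `q`.
#' @param S gating vector (length N).
#' @param consts a [hemodynamic_constants()] object.
#' @return List of derivative vectors `dz`, `df`, `dv`, `dq`.
#' @export
hemo_derivatives <- function(state, S, consts = hemodynamic_constants()) {
  if (any(state$f <= 0) || any(state$v <= 0)) {
    abort("`f` and `v` must be strictly positive (fractional powers)")
  }
  vexp <- state$v^(1 / consts$alpha)
  E <- 1 - (1 - consts$rho)^(1 / state$f) # oxygen extraction at inflow f
  list(
    dz = S - consts$kappa * state$z - consts$gamma * (state$f - 1),
    df = state$z,
    dv = (state$f - vexp) / consts$tau,
    dq = (state$f / consts$rho * E - state$q * vexp / state$v) / consts$tau
  )
}

#' BOLD kernel weights
#'
#' The three weights of the BOLD observation equation at field strength `B0`:
#' `k1 = 4.3 * theta0 * rho * TE` with `theta0 = 28.265 * B0`,
#' `k2 = epsilon * r0 * rho * TE`, and `k3 = 1 - epsilon`.
#'
#' @param consts a [hemodynamic_constants()] object.
#' @return Named numeric vector `c(k1, k2, k3)`.
#' @export
#' @examples
#' bold_kernel_constants() # k3 = 0.53 at the defaults
bold_kernel_constants <- function(consts = hemodynamic_constants()) {
  theta0 <- 28.265 * consts$B0
  c(k1 = 4.3 * theta0 * consts$rho * consts$TE,
    k2 = consts$epsilon * consts$r0 * consts$rho * consts$TE,
    k3 = 1 - consts$epsilon)
}

#' BOLD observation equation
#'
#' `BOLD = V0 [k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v)]`, evaluated
#' elementwise. Zero at the resting state.
#'
#' @inheritParams hemo_derivatives
#' @return BOLD vector (unitless), length N.
#' @export
bold_signal <- function(state, consts = hemodynamic_constants()) {
  if (any(state$v <= 0)) abort("`v` must be strictly positive")
  k <- bold_kernel_constants(consts)
  as.double(consts$V0 * (k["k1"] * (1 - state$q) +
                           k["k2"] * (1 - state$q / state$v) +
                           k["k3"] * (1 - state$v)))
}

#' Simulate BOLD from a gating trajectory
#'
#' Euler-integrates the Balloon-Windkessel ODEs from rest, driven by the
#' gating trajectory at its own step `dt` (optionally with `substeps`
#' hemodynamic sub-steps per neural step), and records the BOLD signal once
#' per `tr` seconds. Fully deterministic given its inputs.
#'
#' @param traj a [simulate_neural()] trajectory (or bare T x N gating matrix,
#'   in which case `dt` must be supplied).
#' @param consts a [hemodynamic_constants()] object.
#' @param tr BOLD sampling interval in seconds; must be an integer multiple
#'   of the trajectory step.
#' @param dt trajectory step when `traj` is a bare matrix.
#' @param substeps hemodynamic sub-steps per neural step (default 1).
#' @param burn_in seconds of BOLD discarded from the start of the output,
#'   after integration (default 0). The hemodynamic system starts at rest,
#'   so the initial transient it shares across regions should be dropped
#'   before computing FC.
#' @param use_compiled use the compiled loop (default); the pure-R loop is
#'   kept for verification.
#' @return An object of class `bold_time_series`: list with `Y`
#'   (floor(T * dt / tr) x N BOLD matrix) and `tr`.
#' @export
simulate_bold <- function(traj, consts = hemodynamic_constants(), tr = 2,
                          dt = NULL, substeps = 1L, burn_in = 0,
                          use_compiled = TRUE) {
  if (inherits(traj, "neural_trajectory")) {
    S_series <- traj$S_series
    dt <- traj$dt
  } else {
    S_series <- traj
    if (is.null(dt)) abort("`dt` is required when `traj` is a bare matrix")
  }
  check_scalar(tr, "tr", lower = 0, strict = TRUE)
  k_sub <- round(tr / dt)
  if (k_sub < 1 || abs(k_sub * dt - tr) > 1e-9) {
    abort(sprintf("`tr` (%g) must be an integer multiple of dt (%g)", tr, dt))
  }
  N <- ncol(S_series)

  if (use_compiled) {
    kk <- bold_kernel_constants(consts)
    Y <- cpp_simulate_bold(S_series, dt, consts$kappa, consts$gamma,
                           consts$tau, consts$alpha, consts$rho, consts$V0,
                           kk["k1"], kk["k2"], kk["k3"],
                           as.integer(k_sub), as.integer(substeps))
  } else {
    state <- hemodynamic_state(N)
    h <- dt / substeps
    n_out <- nrow(S_series) %/% k_sub
    Y <- matrix(NA_real_, n_out, N)
    row <- 0L
    for (t in seq_len(nrow(S_series))) {
      for (s in seq_len(substeps)) {
        d <- hemo_derivatives(state, S_series[t, ], consts)
        state$z <- state$z + h * d$dz
        state$f <- state$f + h * d$df
        state$v <- state$v + h * d$dv
        state$q <- state$q + h * d$dq
      }
      if (t %% k_sub == 0) {
        row <- row + 1L
        Y[row, ] <- bold_signal(state, consts)
      }
    }
  }
  check_scalar(burn_in, "burn_in", lower = 0)
  n_drop <- round(burn_in / tr)
  if (n_drop > 0) {
    if (n_drop >= nrow(Y)) abort("`burn_in` leaves no BOLD samples")
    Y <- Y[-seq_len(n_drop), , drop = FALSE]
  }
  structure(list(Y = Y, tr = tr), class = "bold_time_series")
}

#' @export
print.bold_time_series <- function(x, ...) {
  cat(sprintf("<bold_time_series> %d samples x %d regions, tr = %g s\n",
              nrow(x$Y), ncol(x$Y), x$tr))
  invisible(x)
}

#' Write a BOLD time series as delimited text
#'
#' One row per sample, one column per region, tab-separated with a header of
#' region labels.
#'
#' @param bold a [simulate_bold()] result.
#' @param path output file.
#' @param labels optional region labels for the header.
#' @export
write_bold <- function(bold, path, labels = NULL) {
  Y <- bold$Y
  colnames(Y) <- labels %||% paste0("R", seq_len(ncol(Y)))
  write.table(format(Y, digits = 17, trim = TRUE, scientific = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
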