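#' Population firing-rate transfer function
#'
#' Input-output transfer of the mean-field population:
#' `H(x) = (a x - b) / (1 - exp(-d (a x - b)))`, with the removable
#' singularity at `a x = b` filled by its limit `1/d`. `H` is continuous,
#' strictly increasing, and strictly positive for all finite input currents.
#'
#' @param x input current(s) in nA; any finite numeric vector.
#' @param consts a [synaptic_constants()] object.
#' @return Firing rate(s) in Hz, same length as `x`.
#' @export
#' @examples
#' firing_rate(108 / 270) # at the singularity: 1 / d
firing_rate <- function(x, consts = synaptic_constants()) {
  if (!is.numeric(x) || !all(is.finite(x))) {
    abort("`x` must be finite numeric")
  }
  u <- consts$a * x - consts$b
  denom <- -expm1(-consts$d * u)
  out <- ifelse(u == 0 | denom == 0, 1 / consts$d, u / denom)
  as.double(out)
}

#' Total input current per region
#'
#' `x_i = w_i J S_i + G J sum_j C_ij S_j + I_i`: recurrent self-excitation,
#' structurally-routed long-range input, and constant subcortical drive.
#'
#' @param S gating vector (length N).
#' @param params a [regional_parameters()] object.
#' @param sc a [structural_connectome()] (or bare N x N coupling matrix).
#' @param consts a [synaptic_constants()] object.
#' @return Input-current vector in nA (length N).
#' @export
total_input <- function(S, params, sc, consts = synaptic_constants()) {
  C <- if (inherits(sc, "structural_connectome")) sc$C else sc
  N <- length(S)
  if (!is_square(C) || nrow(C) != N || length(params$w) != N) {
    abort("dimension mismatch between `S`, `params`, and `sc`")
  }
  as.double(params$w * (consts$J * S) +
              (params$G * consts$J) * (C %*% S) + params$I)
}

#' Construct a neural state
#'
#' @param S gating vector in `[0, 1]`.
#' @param x most recent total input currents (optional, defaults to NA).
#' @param t elapsed time in seconds.
#' @return An object of class `neural_state`.
#' @export
neural_state <- function(S, x = rep(NA_real_, length(S)), t = 0) {
  if (any(S < 0 | S > 1)) abort("`S` must lie in [0, 1]")
  structure(list(S = as.double(S), x = as.double(x), t = t),
            class = "neural_state")
}

#' One Euler-Maruyama step of the gating dynamics
#'
#' Advances `dS = [-S/tau_s + r (1 - S) H(x)] dt + sigma sqrt(dt) * noise`,
#' recomputing the input current from the incoming gating first, then clamping
#' the updated gating to `[0, 1]` so it keeps its meaning as a fraction of
#' open channels. The number of clamped entries is returned in the
#' `"clamped"` attribute.
#'
#' @param state a [neural_state()].
#' @param params,sc,consts model objects as in [total_input()].
#' @param dt integration step in seconds (> 0).
#' @param noise standard-normal draw, length N.
#' @return The updated `neural_state`.
#' @export
neural_step <- function(state, params, sc, consts = synaptic_constants(),
                        dt, noise) {
  check_scalar(dt, "dt", lower = 0, strict = TRUE)
  S <- state$S
  if (length(noise) != length(S)) abort("`noise` must have length N")
  x <- total_input(S, params, sc, consts)
  drift <- -S / consts$tau_s + consts$r * (1 - S) * firing_rate(x, consts)
  S_new <- S + dt * drift + params$sigma * sqrt(dt) * noise
  clamped <- sum(S_new < 0 | S_new > 1)
  out <- neural_state(clip(S_new, 0, 1), x = x, t = state$t + dt)
  attr(out, "clamped") <- clamped
  out
}

#' Simulate the regional gating dynamics on a connectome
#'
#' Integrates the stochastic gating equations by Euler-Maruyama at step `dt`
#' from a uniform start `S(0) = S0`, discards the first `burn_in` seconds,
#' and records every retained step. Identical arguments and seed give a
#' bit-identical trajectory.
#'
#' @param params a [regional_parameters()] object.
#' @param sc a [structural_connectome()] or coupling matrix.
#' @param duration total simulated time in seconds (> `burn_in`).
#' @param dt integration step in seconds (default 0.01).
#' @param burn_in initial interval to discard, seconds (default 30).
#' @param seed integer seed for the noise stream.
#' @param S0 uniform initial gating value (default 0.1).
#' @param consts a [synaptic_constants()] object.
#' @param use_compiled use the compiled integration loop (default). The pure-R
#'   loop draws noise in the same order and reproduces it exactly; it exists
#'   for verification.
#' @return An object of class `neural_trajectory`: list with `S_series`
#'   (T x N gating matrix, `T = round(duration/dt) - round(burn_in/dt)`),
#'   `dt`, `seed`, and `clamp_count`.
#' @export
simulate_neural <- function(params, sc, duration, dt = 0.01, burn_in = 30,
                            seed = 1, S0 = 0.1,
                            consts = synaptic_constants(),
                            use_compiled = TRUE) {
  check_scalar(duration, "duration", lower = 0, strict = TRUE)
  check_scalar(dt, "dt", lower = 0, strict = TRUE)
  check_scalar(burn_in, "burn_in", lower = 0)
  if (burn_in >= duration) abort("`duration` must exceed `burn_in`")
  C <- if (inherits(sc, "structural_connectome")) sc$C else sc
  N <- nrow(C)
  if (length(params$w) != N) abort("`params` and `sc` disagree on N")
  n_steps <- round(duration / dt)
  n_burn <- round(burn_in / dt)

  if (use_compiled) {
    res <- with_seed(seed, cpp_simulate_neural(
      C, params$w, params$I, params$G, params$sigma,
      consts$r, consts$tau_s, consts$a, consts$b, consts$d, consts$J,
      dt, n_steps, n_burn, S0))
    S_series <- res$S_series
    clamp_count <- res$clamp_count
  } else {
    S_series <- matrix(NA_real_, n_steps - n_burn, N)
    clamp_count <- 0
    with_seed(seed, {
      state <- neural_state(rep(S0, N))
      for (t in seq_len(n_steps)) {
        noise <- if (params$sigma > 0) rnorm(N) else numeric(N)
        state <- neural_step(state, params, sc, consts, dt, noise)
        clamp_count <- clamp_count + attr(state, "clamped")
        if (t > n_burn) S_series[t - n_burn, ] <- state$S
      }
    })
  }
  structure(list(S_series = S_series, dt = dt, seed = seed,
                 clamp_count = clamp_count),
            class = "neural_trajectory")
}

#' @export
print.neural_trajectory <- function(x, ...) {
  cat(sprintf("<neural_trajectory> %d steps x %d regions, dt = %g s, seed = %s, %d clamps\n",
              nrow(x$S_series), ncol(x$S_series), x$dt,
              format(x$seed), x$clamp_count))
  invisible(x)
}
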