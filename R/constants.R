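#' Synaptic kinetic constants of the mean-field model
#'
#' Fixed kinetic parameters of the reduced mean-field neural dynamics. The
#' defaults are the standard values for this model family: kinetic scalar
#' `r = 0.641`, synaptic time constant `tau_s = 0.1` s, transfer-function gain
#' `a = 270` (per nA of input current, so that `a * x` is in Hz), threshold
#' `b = 108` Hz, shape `d = 0.154` s, and synaptic coupling `J = 0.2609` nA.
#'
#' @param r unitless kinetic scalar.
#' @param tau_s synaptic time constant in seconds.
#' @param a transfer-function gain (Hz per nA).
#' @param b transfer-function threshold (Hz).
#' @param d transfer-function shape parameter (s).
#' @param J synaptic coupling (nA).
#' @return An object of class `synaptic_constants` (a validated list).
#' @export
#' @examples
#' synaptic_constants()
synaptic_constants <- function(r = 0.641, tau_s = 0.1, a = 270, b = 108,
                               d = 0.154, J = 0.2609) {
  out <- list(r = r, tau_s = tau_s, a = a, b = b, d = d, J = J)
  for (nm in names(out)) check_scalar(out[[nm]], nm, lower = 0, strict = TRUE)
  structure(out, class = "synaptic_constants")
}

#' Balloon-Windkessel hemodynamic constants
#'
#' Fixed parameters of the hemodynamic forward model mapping synaptic gating
#' to BOLD. Defaults: signal decay rate `kappa = 0.65` 1/s, flow-dependent
#' elimination rate `gamma = 0.41` 1/s, hemodynamic transit time `tau = 0.98`
#' s, Grubb's exponent `alpha = 0.32`, resting oxygen extraction fraction
#' `rho = 0.34`, resting blood volume fraction `V0 = 0.02`, field strength
#' `B0 = 3` T, echo time `TE = 0.030` s, intravascular relaxation rate
#' `r0 = 110` Hz, and intra/extravascular signal ratio `epsilon = 0.47`.
#'
#' The frequency offset at the outer surface of magnetized vessels is always
#' derived as `theta0 = 28.265 * B0`; it is never stored independently.
#'
#' @param kappa,gamma,tau,alpha,rho,V0,B0,TE,r0,epsilon see Description.
#' @return An object of class `hemodynamic_constants`.
#' @seealso [bold_kernel_constants()] for the derived BOLD kernel weights.
#' @export
hemodynamic_constants <- function(kappa = 0.65, gamma = 0.41, tau = 0.98,
                                  alpha = 0.32, rho = 0.34, V0 = 0.02,
                                  B0 = 3, TE = 0.030, r0 = 110,
                                  epsilon = 0.47) {
  out <- list(kappa = kappa, gamma = gamma, tau = tau, alpha = alpha,
              rho = rho, V0 = V0, B0 = B0, TE = TE, r0 = r0,
              epsilon = epsilon)
  for (nm in names(out)) check_scalar(out[[nm]], nm, lower = 0, strict = TRUE)
  if (rho >= 1) abort("`rho` must be < 1")
  if (epsilon >= 1) abort("`epsilon` must be < 1")
  structure(out, class = "hemodynamic_constants")
}

#' Regional model parameters
#'
#' The object of inference: per-region recurrent connection strength `w` and
#' subcortical input strength `I` (nA), plus the global coupling scale `G` and
#' the neuronal noise amplitude `sigma`, which stay global scalars.
#'
#' @param w numeric vector of recurrent connection strengths (length N).
#' @param I numeric vector of subcortical input strengths in nA (length N).
#' @param G global scaling factor applied to the structural coupling.
#' @param sigma neuronal noise amplitude (>= 0).
#' @return An object of class `regional_parameters`.
#' @export
#' @examples
#' regional_parameters(w = rep(0.5, 4), I = rep(0.3, 4), G = 0.5, sigma = 0.01)
regional_parameters <- function(w, I, G = 0.5, sigma = 0.01) {
  w <- as.double(w); I <- as.double(I)
  if (length(w) != length(I)) abort("`w` and `I` must have equal length")
  if (!all(is.finite(w)) || any(w < 0)) abort("`w` must be finite and >= 0")
  if (!all(is.finite(I)) || any(I < 0)) abort("`I` must be finite and >= 0")
  check_scalar(G, "G", lower = 0)
  check_scalar(sigma, "sigma", lower = 0)
  structure(list(w = w, I = I, G = G, sigma = sigma),
            class = "regional_parameters")
}

#' @export
print.regional_parameters <- function(x, ...) {
  cat(sprintf("<regional_parameters> N = %d regions\n", length(x$w)))
  cat(sprintf("  w: mean %.3f [%.3f, %.3f]\n", mean(x$w), min(x$w), max(x$w)))
  cat(sprintf("  I: mean %.3f [%.3f, %.3f]\n", mean(x$I), min(x$I), max(x$I)))
  cat(sprintf("  G = %.4g, sigma = %.4g\n", x$G, x$sigma))
  invisible(x)
}

n_regions <- function(x) UseMethod("n_regions")

#' @export
n_regions.regional_parameters <- function(x) length(x$w)

#' @export
n_regions.structural_connectome <- function(x) nrow(x$C)
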