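#' Membrane parameter set
#'
#' Bundles the electrical constants of a single-compartment
#' Hodgkin-Huxley membrane together with the channel counts used by the
#' stochastic simulators.  Channel counts are derived from densities as
#' `round(density * area)` unless given explicitly.
#'
#' Defaults are the standard shifted Hodgkin-Huxley values
#' (C_m = 1 uF/cm^2, g_Na = 120, g_K = 36, g_L = 0.3 mS/cm^2,
#' E_Na = 50, E_K = -77, E_L = -54.387 mV) with channel densities
#' rho_Na = 60/um^2 and rho_K = 18/um^2, so the default 100 um^2 patch
#' carries 6,000 Na and 1,800 K channels.
#'
#' @param C_m membrane capacitance (uF/cm^2), > 0.
#' @param g_Na,g_K,g_L maximal Na, K and leak conductances (mS/cm^2), >= 0.
#' @param E_Na,E_K,E_L reversal potentials (mV); `E_Na > E_K` is enforced.
#' @param area membrane area (um^2), > 0.
#' @param rho_Na,rho_K channel densities (channels/um^2).
#' @param N_Na,N_K channel counts; default `round(rho * area)`, each >= 1.
#' @return A list of class `membrane_params`.
#' @examples
#' p <- membrane_params()
#' p$N_Na  # 6000
#' @export
membrane_params <- function(C_m = 1, g_Na = 120, g_K = 36, g_L = 0.3,
                            E_Na = 50, E_K = -77, E_L = -54.387,
                            area = 100, rho_Na = 60, rho_K = 18,
                            N_Na = NULL, N_K = NULL) {
  if (!is.finite(C_m) || C_m <= 0) stop("C_m must be > 0")
  for (g in c(g_Na, g_K, g_L))
    if (!is.finite(g) || g < 0) stop("conductances must be >= 0")
  if (!all(is.finite(c(E_Na, E_K, E_L)))) stop("reversal potentials must be finite")
  if (E_Na <= E_K) stop("E_Na must exceed E_K")
  if (!is.finite(area) || area <= 0) stop("area must be > 0")
  if (is.null(N_Na)) N_Na <- round(rho_Na * area)
  if (is.null(N_K)) N_K <- round(rho_K * area)
  if (N_Na < 1 || N_K < 1) stop("channel counts must be >= 1")
  structure(list(C_m = C_m, g_Na = g_Na, g_K = g_K, g_L = g_L,
                 E_Na = E_Na, E_K = E_K, E_L = E_L,
                 area = area, rho_Na = rho_Na, rho_K = rho_K,
                 N_Na = as.integer(round(N_Na)), N_K = as.integer(round(N_K))),
            class = "membrane_params")
}

#' @export
print.membrane_params <- function(x, ...) {
  cat("Hodgkin-Huxley membrane parameters\n")
  cat(sprintf("  C_m = %g uF/cm^2; g_Na/g_K/g_L = %g/%g/%g mS/cm^2\n",
              x$C_m, x$g_Na, x$g_K, x$g_L))
  cat(sprintf("  E_Na/E_K/E_L = %g/%g/%g mV\n", x$E_Na, x$E_K, x$E_L))
  cat(sprintf("  area = %g um^2; N_Na = %d, N_K = %d channels\n",
              x$area, x$N_Na, x$N_K))
  invisible(x)
}

#' Resting state of the deterministic membrane
#'
#' Solves the zero-current steady state
#' \eqn{g_{Na} m_\infty^3 h_\infty (E_{Na}-V) + g_K n_\infty^4 (E_K-V)
#'      + g_L (E_L-V) = 0}
#' for the resting potential and returns the corresponding steady-state
#' gating triple.
#'
#' @param params a [membrane_params()] object.
#' @param interval search interval for the resting potential (mV).
#' @return List with `V` (mV) and gating values `m`, `h`, `n`.
#' @export
resting_state <- function(params = membrane_params(),
                          interval = c(-90, -40)) {
  f <- function(V) {
    s <- hh_steady_state(V)
    params$g_Na * s$m^3 * s$h * (params$E_Na - V) +
      params$g_K * s$n^4 * (params$E_K - V) +
      params$g_L * (params$E_L - V)
  }
  V <- uniroot(f, interval, tol = 1e-12)$root
  s <- hh_steady_state(V)
  list(V = V, m = s$m, h = s$h, n = s$n)
}
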