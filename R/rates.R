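#' Hodgkin-Huxley voltage-dependent rate functions
#'
#' Evaluates the six subunit transition rates of the classical
#' Hodgkin-Huxley model at one or more voltages, together with the derived
#' per-subunit steady states and time constants.  The modern shifted
#' parameterization is used (resting potential near -65 mV):
#' \deqn{\alpha_m = 0.1 (V+40) / (1 - e^{-(V+40)/10}), \quad
#'       \beta_m = 4 e^{-(V+65)/18}}
#' \deqn{\alpha_h = 0.07 e^{-(V+65)/20}, \quad
#'       \beta_h = 1 / (1 + e^{-(V+35)/10})}
#' \deqn{\alpha_n = 0.01 (V+55) / (1 - e^{-(V+55)/10}), \quad
#'       \beta_n = 0.125 e^{-(V+65)/80}}
#' with V in mV and rates in 1/ms.  The removable singularities of
#' \eqn{\alpha_m} (at -40 mV) and \eqn{\alpha_n} (at -55 mV) are evaluated by
#' a series-expansion branch within 1e-7 mV of the singular voltage.
#'
#' @param V numeric vector of membrane voltages (mV); must be finite.
#' @return A data frame with one row per voltage and columns `V`,
#'   `alpha_m`, `beta_m`, `alpha_h`, `beta_h`, `alpha_n`, `beta_n` (1/ms),
#'   steady states `m_inf`, `h_inf`, `n_inf`, and time constants `tau_m`,
#'   `tau_h`, `tau_n` (ms).
#' @examples
#' hh_rates(c(-65, -40))
#' @export
hh_rates <- function(V) {
  if (!is.numeric(V) || any(!is.finite(V)))
    stop("V must be a finite numeric vector")
  r <- cpp_hh_rates(as.numeric(V))
  out <- as.data.frame(r)
  out <- cbind(V = as.numeric(V), out)
  out$m_inf <- out$alpha_m / (out$alpha_m + out$beta_m)
  out$h_inf <- out$alpha_h / (out$alpha_h + out$beta_h)
  out$n_inf <- out$alpha_n / (out$alpha_n + out$beta_n)
  out$tau_m <- 1 / (out$alpha_m + out$beta_m)
  out$tau_h <- 1 / (out$alpha_h + out$beta_h)
  out$tau_n <- 1 / (out$alpha_n + out$beta_n)
  out
}

#' Steady-state gating triple at a clamped voltage
#'
#' @param V scalar voltage (mV).
#' @return Named list with elements `m`, `h`, `n` (the per-subunit
#'   steady-state open fractions) and `V`.
#' @export
hh_steady_state <- function(V) {
  r <- hh_rates(V[1])
  list(m = r$m_inf, h = r$h_inf, n = r$n_inf, V = V[1])
}
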