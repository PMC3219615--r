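# ---- applied-current plumbing -------------------------------------------

# expand a current specification (scalar DC, function of time, or per-step
# vector) to one value per Euler step
current_vector <- function(I, n_steps, dt) {
  if (is.function(I)) {
    vapply((seq_len(n_steps) - 1) * dt, I, 0.0)
  } else if (length(I) == 1) {
    rep(as.numeric(I), n_steps)
  } else if (length(I) == n_steps) {
    as.numeric(I)
  } else if (length(I) == n_steps + 1) {
    as.numeric(I[seq_len(n_steps)])
  } else stop("current waveform length does not match the time grid")
}

# assemble the standard trace data frame
make_trace <- function(time, V, I, extra = list(), model, dt, seed = NULL) {
  df <- data.frame(time_ms = time, V_mV = V,
                   I_uAcm2 = c(I, I[length(I)]))
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  attr(df, "model") <- model
  attr(df, "dt") <- dt
  attr(df, "seed") <- seed
  class(df) <- c("voltage_trace", "data.frame")
  df
}

check_time_args <- function(T, dt) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (!is.finite(T) || T < dt) stop("T must be >= dt")
}

default_init <- function(params, init) {
  if (is.null(init)) resting_state(params) else init
}

check_seed <- function(seed) {
  if (is.null(seed) || !is.finite(seed))
    stop("a finite integer seed is required for stochastic simulation")
  as.numeric(seed)
}

# deterministic integer allocation of N channels to the stationary vector
round_counts <- function(p, N) {
  raw <- p * N
  base <- floor(raw)
  rem <- N - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

MODEL_CHOICES <- c("deterministic", "markov", "current", "subunit",
                   "subunit_independent", "ou", "ou_shared", "ssa")

#' Integrate the deterministic Hodgkin-Huxley equations
#'
#' Fixed-step forward Euler on the voltage and gating equations, with
#' conductance terms \eqn{\bar g_{Na} m^3 h} and \eqn{\bar g_K n^4}.  The
#' stochastic steppers in this package share the same update rule, so their
#' zero-noise limits reproduce this trajectory bit-for-bit.
#'
#' @param params a [membrane_params()] object.
#' @param I applied current (uA/cm^2): scalar DC, function of time (ms), or
#'   vector with one value per step.
#' @param T duration (ms).
#' @param dt time step (ms); default 0.01.
#' @param init initial state, a list with `V`, `m`, `h`, `n`; defaults to
#'   the resting state.
#' @return A `voltage_trace` data frame with columns `time_ms`, `V_mV`,
#'   `I_uAcm2`, `m`, `h`, `n`, `open_frac_Na`, `open_frac_K`.
#' @examples
#' tr <- simulate_deterministic(membrane_params(), I = 10, T = 50)
#' range(tr$V_mV)
#' @export
simulate_deterministic <- function(params = membrane_params(), I = 0,
                                   T = 100, dt = 0.01, init = NULL) {
  check_time_args(T, dt)
  init <- default_init(params, init)
  n_steps <- round(T / dt)
  Iv <- current_vector(I, n_steps, dt)
  out <- cpp_det_neuron(unclass(params), Iv, dt, init$V, init$m, init$h, init$n)
  make_trace((0:n_steps) * dt, out$V, Iv,
             extra = list(m = out$m, h = out$h, n = out$n,
                          open_frac_Na = out$open_frac_Na,
                          open_frac_K = out$open_frac_K),
             model = "deterministic", dt = dt)
}

#' Simulate a stochastic Hodgkin-Huxley neuron
#'
#' Runs one of the channel-noise models with the membrane voltage evolving
#' freely under an applied current:
#' \describe{
#'   \item{`deterministic`}{the noiseless reference model.}
#'   \item{`markov`}{exact Markov-chain channel states (Gillespie-type, the
#'     gold standard): transitions are simulated with rates frozen over each
#'     voltage step; voltage is advanced by forward Euler on the counted
#'     conducting fractions.}
#'   \item{`current`}{deterministic gating plus white-noise current of
#'     intensity `sigma_I` in the voltage equation.}
#'   \item{`subunit`}{Euler-Maruyama gating SDEs with noise variance
#'     \eqn{(\alpha(1-x) + \beta x)/N} per gate, gates clipped to `[0,1]`.}
#'   \item{`subunit_independent`}{the independent-copies variant: 3 m-copies
#'     + 1 h-copy and 4 n-copies, conducting fractions
#'     \eqn{m_1 m_2 m_3 h} and \eqn{n_1 n_2 n_3 n_4}.}
#'   \item{`ou` / `ou_shared`}{voltage-clamp conductance noise: the
#'     deterministic open fractions (carried by the gating ODE) plus a sum
#'     of Ornstein-Uhlenbeck components with voltage-dependent timescales
#'     and variances (see [build_ou_bank()]); `ou_shared` drives all
#'     components of a channel type with a single Wiener increment.}
#'   \item{`ssa`}{the system-size conductance model: zero-mean channel-state
#'     fluctuation vectors driven by the linear SDE with generator drift and
#'     matrix-square-root diffusion evaluated at the deterministic state;
#'     conducting fractions are the deterministic values plus the
#'     fluctuation's conducting component, floored at 0 in the voltage
#'     equation.}
#' }
#'
#' @inheritParams simulate_deterministic
#' @param model one of `"deterministic"`, `"markov"`, `"current"`,
#'   `"subunit"`, `"subunit_independent"`, `"ou"`, `"ou_shared"`, `"ssa"`.
#' @param seed integer seed (required for stochastic models).
#' @param sigma_I white-noise current intensity (uA/cm^2 sqrt(ms)) for the
#'   current-noise model.
#' @param N_Na,N_K channel counts; default taken from `params`.  `Inf`
#'   disables the channel noise (the zero-noise limit).
#' @param record_states for `model = "markov"`: also return the integer
#'   occupancy of every channel configuration.
#' @param record_fluct for `model = "ssa"`: also return the fluctuation
#'   vectors at every step.
#' @return A `voltage_trace` data frame; stochastic models add
#'   `open_frac_Na` / `open_frac_K` columns, and extras are attached as
#'   attributes (`occupancy_Na`, `occupancy_K`, `fluct_Na`, `fluct_K`,
#'   `cons_Na`, `cons_K`) when recorded.
#' @examples
#' tr <- simulate_neuron("subunit", T = 20, seed = 1)
#' @export
simulate_neuron <- function(model = MODEL_CHOICES, params = membrane_params(),
                            I = 0, T = 100, dt = 0.01, seed = NULL,
                            init = NULL, sigma_I = 0,
                            N_Na = params$N_Na, N_K = params$N_K,
                            record_states = FALSE, record_fluct = FALSE) {
  model <- match.arg(model)
  check_time_args(T, dt)
  init <- default_init(params, init)
  n_steps <- round(T / dt)
  Iv <- current_vector(I, n_steps, dt)
  time <- (0:n_steps) * dt
  inv_NNa <- if (is.finite(N_Na)) 1 / N_Na else 0
  inv_NK <- if (is.finite(N_K)) 1 / N_K else 0
  p <- unclass(params)

  if (model == "deterministic")
    return(simulate_deterministic(params, I, T, dt, init))

  seed <- check_seed(seed)
  if (model == "markov") {
    if (!is.finite(N_Na) || !is.finite(N_K))
      stop("the Markov-chain model requires finite channel counts")
    sna <- hh_na_scheme(); sk <- hh_k_scheme()
    c0na <- round_counts(gating_to_statevec(init, sna), N_Na)
    c0k <- round_counts(gating_to_statevec(init, sk), N_K)
    out <- cpp_mc_neuron(p, scheme_for_cpp(sna), scheme_for_cpp(sk),
                         as.integer(N_Na), as.integer(N_K), Iv, dt, init$V,
                         c0na, c0k, seed, record_states)
    tr <- make_trace(time, out$V, Iv,
                     extra = list(open_frac_Na = out$open_frac_Na,
                                  open_frac_K = out$open_frac_K),
                     model = model, dt = dt, seed = seed)
    if (record_states) {
      attr(tr, "occupancy_Na") <- out$occupancy_Na
      attr(tr, "occupancy_K") <- out$occupancy_K
    }
    return(tr)
  }

  out <- switch(model,
    current = cpp_current_neuron(p, Iv, dt, init$V, init$m, init$h, init$n,
                                 sigma_I, seed),
    subunit = cpp_subunit_neuron(p, Iv, dt, init$V, init$m, init$h, init$n,
                                 inv_NNa, inv_NK, seed),
    subunit_independent = cpp_subunit_copies_neuron(
      p, Iv, dt, init$V, init$m, init$h, init$n, inv_NNa, inv_NK, seed),
    ou = cpp_ou_neuron(p, Iv, dt, init$V, init$m, init$h, init$n,
                       inv_NNa, inv_NK, FALSE, seed, TRUE),
    ou_shared = cpp_ou_neuron(p, Iv, dt, init$V, init$m, init$h, init$n,
                              inv_NNa, inv_NK, TRUE, seed, TRUE),
    ssa = cpp_ssa_neuron(p, Iv, dt, init$V, init$m, init$h, init$n,
                         inv_NNa, inv_NK, seed, record_fluct))
  extra <- list(open_frac_Na = out$open_frac_Na, open_frac_K = out$open_frac_K)
  if (!is.null(out$m)) extra <- c(extra, list(m = out$m, h = out$h, n = out$n))
  tr <- make_trace(time, out$V, Iv, extra = extra, model = model,
                   dt = dt, seed = seed)
  if (model == "ssa") {
    attr(tr, "cons_Na") <- out$cons_Na
    attr(tr, "cons_K") <- out$cons_K
    if (record_fluct) {
      attr(tr, "fluct_Na") <- out$fluct_Na
      attr(tr, "fluct_K") <- out$fluct_K
    }
  }
  tr
}
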