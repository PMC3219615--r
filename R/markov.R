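#' Exact clamped Gillespie simulation of a channel population
#'
#' Simulates `N` independent channels of one kinetic scheme at a fixed
#' clamp voltage as a continuous-time Markov chain: aggregate propensities
#' are `rate(k -> l, V) * count_k`, waiting times are exponential, and the
#' occupancy vector is recorded on a uniform grid by sample-and-hold.
#'
#' @param scheme a [kinetic_scheme()]; arbitrary R-function rates are
#'   allowed (they are evaluated once at the clamp voltage).
#' @param N number of channels (>= 1).
#' @param V clamp voltage (mV).
#' @param T duration (ms), > 0.
#' @param record_dt recording interval (ms); default 0.1.
#' @param seed integer seed.
#' @param init `"stationary"` (counts allocated to the stationary
#'   distribution of the generator at `V`) or an integer vector of initial
#'   counts summing to `N`.
#' @return Data frame with `time_ms`, one occupancy column per state, and
#'   `open_frac` (fraction of channels in conducting states).
#' @examples
#' occ <- simulate_markov_clamped(hh_k_scheme(), N = 100, V = -40,
#'                                T = 50, seed = 1)
#' mean(occ$open_frac)
#' @export
simulate_markov_clamped <- function(scheme, N, V, T, record_dt = 0.1,
                                    seed = NULL, init = "stationary") {
  if (N < 1) stop("N must be >= 1")
  if (T <= 0) stop("T must be > 0")
  seed <- check_seed(seed)
  if (identical(init, "stationary")) {
    counts0 <- round_counts(stationary_statevec(scheme, V), N)
  } else {
    counts0 <- as.integer(init)
    if (length(counts0) != length(scheme$states) || sum(counts0) != N)
      stop("init counts must cover all states and sum to N")
  }
  occ <- cpp_gillespie_clamped(scheme_for_cpp(scheme, V = V), counts0,
                               V, T, record_dt, seed)
  colnames(occ) <- scheme$states
  df <- data.frame(time_ms = (seq_len(nrow(occ)) - 1) * record_dt)
  df <- cbind(df, as.data.frame(occ))
  df$open_frac <- rowSums(occ[, scheme$open_states, drop = FALSE]) / N
  df
}

#' Event log of a clamped Gillespie run
#'
#' Returns individual transition events (time, from-state, to-state) for
#' dwell-time analyses; intended for small channel numbers.
#'
#' @inheritParams simulate_markov_clamped
#' @param init integer vector of initial counts.
#' @param max_events cap on the number of recorded events.
#' @return Data frame with `time_ms`, `from`, `to` (state labels).
#' @export
markov_events <- function(scheme, init, V, T, seed = NULL,
                          max_events = 1e6) {
  seed <- check_seed(seed)
  ev <- cpp_gillespie_events(scheme_for_cpp(scheme, V = V),
                             as.integer(init), V, T, seed,
                             as.integer(max_events))
  data.frame(time_ms = ev$time_ms,
             from = scheme$states[ev$from],
             to = scheme$states[ev$to])
}

#' Stationary state-fraction vector of a scheme at fixed voltage
#'
#' The normalized null vector of the generator [build_generator()]; for
#' subunit-factorizable schemes this equals the multinomial combination of
#' the steady-state gating variables.
#'
#' @inheritParams simulate_markov_clamped
#' @return Named probability vector over states.
#' @export
stationary_statevec <- function(scheme, V) {
  A <- build_generator(scheme, V)
  dec <- eigen(A)
  k <- which.min(abs(dec$values))
  v <- Re(dec$vectors[, k])
  v <- v / sum(v)
  if (any(v < -1e-10)) stop("stationary vector has negative entries")
  setNames(pmax(v, 0) / sum(pmax(v, 0)), scheme$states)
}
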