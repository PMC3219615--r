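#' Ornstein-Uhlenbeck bank for voltage-clamp conductance noise
#'
#' In voltage clamp the stationary open-channel fraction of a
#' subunit-factorizable scheme is binomial, and its autocovariance is a
#' finite sum of exponentials; the conductance fluctuation can therefore be
#' represented as a sum of independent OU components.  For the classical K
#' scheme the components are k = 1..4 with
#' \deqn{\tau_k = \tau_n / k, \qquad
#'       v_k = \binom{4}{k} n_\infty^{2(4-k)} (n_\infty(1-n_\infty))^k / N_K,}
#' and for the classical Na scheme (i,j) in \{0..3\}x\{0,1\} minus (0,0) with
#' \deqn{\tau_{ij} = 1 / (i/\tau_m + j/\tau_h), \qquad
#'       v_{ij} = \binom{3}{i} (m_\infty^2)^{3-i} (m_\infty(1-m_\infty))^i
#'                (h_\infty^2)^{1-j} (h_\infty(1-h_\infty))^j / N.}
#' The total stationary variance \eqn{\sum_i v_i} equals the binomial value
#' \eqn{p_\infty(1-p_\infty)/N} exactly.
#'
#' @param type `"Na"` (7 components) or `"K"` (4 components); alternatively
#'   a factorizable [kinetic_scheme()].
#' @param V clamp voltage (mV).
#' @param N channel count.
#' @return A data frame with one row per OU component: `label`, `tau` (ms)
#'   and `v` (stationary variance, dimensionless); attributes `p_inf`
#'   (stationary open probability) and `total_var`.
#' @examples
#' b <- build_ou_bank("K", V = -40, N = 1800)
#' sum(b$v) - attr(b, "p_inf") * (1 - attr(b, "p_inf")) / 1800  # 0
#' @export
build_ou_bank <- function(type, V, N) {
  if (inherits(type, "kinetic_scheme")) {
    if (is.null(type$factorization))
      stop("scheme has no subunit factorization; OU bank undefined")
    type <- if (type$factorization == "na") "Na" else "K"
  }
  type <- match.arg(type, c("Na", "K"))
  r <- hh_rates(V)
  if (type == "K") {
    k <- 1:4
    tau <- r$tau_n / k
    v <- choose(4, k) * r$n_inf^(2 * (4 - k)) *
      (r$n_inf * (1 - r$n_inf))^k / N
    lab <- sprintf("k%d", k)
    p <- r$n_inf^4
  } else {
    grid <- expand.grid(i = 0:3, j = 0:1)
    grid <- grid[!(grid$i == 0 & grid$j == 0), ]
    tau <- 1 / (grid$i / r$tau_m + grid$j / r$tau_h)
    v <- choose(3, grid$i) * (r$m_inf^2)^(3 - grid$i) *
      (r$m_inf * (1 - r$m_inf))^grid$i *
      (r$h_inf^2)^(1 - grid$j) * (r$h_inf * (1 - r$h_inf))^grid$j / N
    lab <- sprintf("i%dj%d", grid$i, grid$j)
    p <- r$m_inf^3 * r$h_inf
  }
  out <- data.frame(label = lab, tau = tau, v = v)
  attr(out, "p_inf") <- p
  attr(out, "total_var") <- sum(v)
  out
}

#' Calibrate the current-noise intensity to a target mean ISI
#'
#' Finds the white-noise current intensity `sigma_I` for which the
#' current-noise model's mean interspike interval at a given DC drive
#' matches a target (typically the Markov-chain model's mean ISI at the
#' same drive), by bisection with Monte-Carlo ISI estimation at each trial
#' intensity.  The mean ISI is a decreasing function of `sigma_I` in the
#' regimes of interest (stronger fluctuations shorten the intervals).
#'
#' @param params a [membrane_params()].
#' @param I_DC constant applied current (uA/cm^2).
#' @param target_mean_isi target mean ISI (ms).
#' @param tol calibration tolerance on the mean ISI (ms), > 0.
#' @param seed integer seed.
#' @param sigma_range initial bracket for `sigma_I`; the upper end is
#'   doubled (up to 4 times) if it does not bracket the target.
#' @param n_spikes number of spikes collected per trial intensity.
#' @param dt time step (ms).
#' @param max_iter bisection iterations.
#' @return List with `sigma_I`, the achieved `mean_isi`, and the number of
#'   bisection iterations `iter`.
#' @export
calibrate_current_noise <- function(params = membrane_params(), I_DC,
                                    target_mean_isi, tol = 0.5, seed = NULL,
                                    sigma_range = c(0, 20), n_spikes = 300,
                                    dt = 0.01, max_iter = 30) {
  if (tol <= 0) stop("tol must be > 0")
  seed <- check_seed(seed)
  rest <- resting_state(params)
  mean_isi_at <- function(sigma, sd) {
    collect_mean_isi(function(T, s)
      simulate_neuron("current", params, I = I_DC, T = T, dt = dt, seed = s,
                      init = rest, sigma_I = sigma),
      n_spikes = n_spikes, seed = sd)
  }
  lo <- sigma_range[1]; hi <- sigma_range[2]
  f_lo <- mean_isi_at(lo, cpp_substream(seed, 1))
  if (is.finite(f_lo) && abs(f_lo - target_mean_isi) <= tol)
    return(list(sigma_I = lo, mean_isi = f_lo, iter = 0L))
  # mean ISI decreases with sigma; need f(lo) > target > f(hi)
  if (is.finite(f_lo) && f_lo < target_mean_isi - tol)
    stop(sprintf(paste0("calibration failure: mean ISI at sigma_I = %g is ",
                        "%.3f ms, already below the target %.3f ms"),
                 lo, f_lo, target_mean_isi))
  f_hi <- mean_isi_at(hi, cpp_substream(seed, 2))
  tries <- 0
  while ((!is.finite(f_hi) || f_hi > target_mean_isi) && tries < 4) {
    hi <- hi * 2; tries <- tries + 1
    f_hi <- mean_isi_at(hi, cpp_substream(seed, 2 + tries))
  }
  if (!is.finite(f_hi) || f_hi > target_mean_isi)
    stop(sprintf(paste0("calibration failure: could not bracket the target ",
                        "mean ISI %.3f ms (mean ISI %.3f ms at sigma_I = %g)"),
                 target_mean_isi, f_hi, hi))
  mid <- NA; f_mid <- NA
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- mean_isi_at(mid, cpp_substream(seed, 100 + it))
    if (is.finite(f_mid) && abs(f_mid - target_mean_isi) <= tol) break
    if (!is.finite(f_mid) || f_mid > target_mean_isi) lo <- mid else hi <- mid
  }
  list(sigma_I = mid, mean_isi = f_mid, iter = it)
}

# run a simulator in chunks until n_spikes spikes are collected; returns the
# mean ISI (NA if the model does not spike within the time budget)
collect_mean_isi <- function(simfun, n_spikes, seed, chunk_T = 2000,
                             max_T = 40000, threshold = -20, dead_time = 2) {
  isis <- numeric(0)
  total_T <- 0
  k <- 0
  while (length(isis) < n_spikes && total_T < max_T) {
    k <- k + 1
    tr <- simfun(chunk_T, cpp_substream(seed, k))
    st <- detect_spikes(tr, threshold, dead_time)
    if (length(st$times) >= 2) isis <- c(isis, diff(st$times))
    total_T <- total_T + chunk_T
  }
  if (length(isis) < 2) return(NA_real_)
  mean(isis)
}
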