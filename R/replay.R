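#' Replayed-trajectory ensemble statistics
#'
#' Drives the channel (or fluctuation) dynamics of a chosen noise model
#' along a prescribed voltage path with the voltage equation disabled, and
#' returns the per-time-point ensemble mean and variance of the conducting
#' fractions across replicates.  Each replicate uses an independent RNG
#' sub-stream derived from the root seed.
#'
#' Initial conditions emulate stationarity at `V_path[1]`: the Markov chain
#' draws a multinomial sample from the stationary occupancy, the OU bank
#' draws its components from their stationary variances, the subunit and
#' system-size models start at the deterministic state (discard an initial
#' burn-in window when comparing to stationary closed forms).
#'
#' @param model one of `"markov"`, `"subunit"`, `"subunit_independent"`,
#'   `"ou"`, `"ou_shared"`, `"ssa"`.
#' @param V_path voltage path: a `voltage_trace` data frame (columns
#'   `time_ms`, `V_mV`) or a numeric vector on a uniform grid of step `dt`.
#' @param reps number of replicates (>= 2).
#' @param seed root integer seed.
#' @param params a [membrane_params()]; supplies `N_Na` / `N_K`.
#' @param N_Na,N_K channel counts (override `params`).
#' @param dt grid step (ms); inferred from `V_path` when it is a trace.
#' @param init initial gating state; defaults to the steady state at
#'   `V_path[1]`.
#' @param rep_seeds optional explicit vector of per-replicate seeds
#'   (overrides `reps`/`seed`); mainly for reproducibility checks.
#' @param substeps integrate the stochastic dynamics at `dt / substeps`
#'   (the voltage path is linearly interpolated; statistics are returned on
#'   the original grid).  Useful for the SDE models, whose Euler-Maruyama
#'   stationary statistics carry an O(dt) bias on fast components.
#' @return An `ensemble_stats` data frame with columns `time_ms`,
#'   `mean_open_Na`, `var_open_Na`, `mean_open_K`, `var_open_K`, and
#'   attribute `reps`.
#' @examples
#' path <- rep(-40, 2001)  # 20 ms of clamp at dt = 0.01
#' es <- replay_ensemble("ou", path, reps = 200, seed = 1, dt = 0.01)
#' @export
replay_ensemble <- function(model = c("markov", "subunit",
                                      "subunit_independent", "ou",
                                      "ou_shared", "ssa"),
                            V_path, reps = 1000, seed = NULL,
                            params = membrane_params(),
                            N_Na = params$N_Na, N_K = params$N_K,
                            dt = NULL, init = NULL, rep_seeds = NULL,
                            substeps = 1) {
  model <- match.arg(model)
  if (is.data.frame(V_path)) {
    tv <- V_path$time_ms
    if (is.null(dt)) dt <- tv[2] - tv[1]
    if (max(abs(diff(tv) - dt)) > 1e-8)
      stop("V_path must be on a strictly uniform time grid")
    V <- V_path$V_mV
  } else {
    if (is.null(dt)) stop("dt is required when V_path is a bare vector")
    V <- as.numeric(V_path)
  }
  if (any(!is.finite(V))) stop("V_path contains non-finite samples")
  if (is.null(rep_seeds) && reps < 2) stop("reps must be >= 2")
  if (is.null(init)) init <- hh_steady_state(V[1])
  substeps <- as.integer(substeps)
  keep_idx <- TRUE
  if (substeps > 1) {
    n0 <- length(V)
    V <- approx(seq_len(n0), V, n = (n0 - 1) * substeps + 1)$y
    dt_out <- dt
    dt <- dt / substeps
    keep_idx <- seq(1, length(V), by = substeps)
  }
  inv_NNa <- if (is.finite(N_Na)) 1 / N_Na else 0
  inv_NK <- if (is.finite(N_K)) 1 / N_K else 0

  run1 <- function(sd, nreps) {
    switch(model,
      markov = {
        sna <- hh_na_scheme(); sk <- hh_k_scheme()
        p0na <- gating_to_statevec(init, sna)
        p0k <- gating_to_statevec(init, sk)
        a <- cpp_markov_replay_ensemble(scheme_for_cpp(sna), as.integer(N_Na),
                                        V, dt, nreps, sd, p0na)
        b <- cpp_markov_replay_ensemble(scheme_for_cpp(sk), as.integer(N_K),
                                        V, dt, nreps, sd, p0k)
        list(mean_Na = a$mean, var_Na = a$var, m4_Na = a$m4,
             mean_K = b$mean, var_K = b$var, m4_K = b$m4)
      },
      subunit = cpp_subunit_replay_ensemble(V, dt, nreps, sd, inv_NNa,
                                            inv_NK, init$m, init$h, init$n,
                                            FALSE),
      subunit_independent = cpp_subunit_replay_ensemble(
        V, dt, nreps, sd, inv_NNa, inv_NK, init$m, init$h, init$n, TRUE),
      ou = cpp_ou_replay_ensemble(V, dt, nreps, sd, inv_NNa, inv_NK,
                                  init$m, init$h, init$n, FALSE),
      ou_shared = cpp_ou_replay_ensemble(V, dt, nreps, sd, inv_NNa, inv_NK,
                                         init$m, init$h, init$n, TRUE),
      ssa = cpp_ssa_replay_ensemble(V, dt, nreps, sd, inv_NNa, inv_NK,
                                    init$m, init$h, init$n))
  }

  if (is.null(rep_seeds)) {
    seed <- check_seed(seed)
    res <- run1(seed, as.integer(reps))
    nreps <- as.integer(reps)
  } else {
    # explicit per-replicate seeds: run single-replicate paths and pool
    paths <- lapply(rep_seeds, function(s) run1(check_seed(s), 1L))
    pool <- function(field) {
      mat <- sapply(paths, function(p) p[[field]])
      list(mean = rowMeans(mat), var = apply(mat, 1, stats::var))
    }
    na <- pool("mean_Na"); k <- pool("mean_K")
    res <- list(mean_Na = na$mean, var_Na = na$var,
                mean_K = k$mean, var_K = k$var)
    nreps <- length(rep_seeds)
  }
  out <- data.frame(time_ms = (seq_along(V) - 1) * dt,
                    mean_open_Na = res$mean_Na, var_open_Na = res$var_Na,
                    mean_open_K = res$mean_K, var_open_K = res$var_K)
  # standard error of the ensemble variance from the empirical fourth moment
  var_se <- function(v, m4, n) {
    if (is.null(m4)) return(rep(NA_real_, length(v)))
    sqrt(pmax(m4 - v^2 * (n - 3) / (n - 1), 0) / n)
  }
  out$se_var_open_Na <- var_se(res$var_Na, res$m4_Na, nreps)
  out$se_var_open_K <- var_se(res$var_K, res$m4_K, nreps)
  if (!isTRUE(keep_idx)) {
    out <- out[keep_idx, , drop = FALSE]
    out$time_ms <- (seq_len(nrow(out)) - 1) * dt_out
    rownames(out) <- NULL
  }
  attr(out, "reps") <- nreps
  attr(out, "model") <- model
  class(out) <- c("ensemble_stats", "data.frame")
  out
}
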