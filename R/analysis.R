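#' Closed-form binomial moments of open-channel fractions along a path
#'
#' For independent channels driven along a prescribed voltage trajectory,
#' the time-varying distribution of the open-channel fraction approaches an
#' asymptotically stable, voltage-dependent binomial law whose moments
#' follow from the deterministic gating solution along the path:
#' \deqn{\mathrm{mean}_{Na}(t) = m(t)^3 h(t), \qquad
#'       \mathrm{mean}_K(t) = n(t)^4,}
#' \deqn{\mathrm{var}_{Na}(t) = m^3 h (1 - m^3 h) / N_{Na}, \qquad
#'       \mathrm{var}_K(t) = n^4 (1 - n^4) / N_K.}
#'
#' @param V_path a `voltage_trace` data frame or numeric voltage vector on
#'   a uniform grid.
#' @param N_Na,N_K channel counts.
#' @param init initial gating state (list with `m`, `h`, `n`); defaults to
#'   the steady state at `V_path[1]`.
#' @param dt grid step (ms); inferred from a trace.
#' @param substeps Euler sub-steps per grid interval (with linear voltage
#'   interpolation) used to integrate the gating ODE accurately.
#' @return Data frame with `time_ms`, `mean_open_Na`, `var_open_Na`,
#'   `mean_open_K`, `var_open_K`, and the gating solution `m`, `h`, `n`.
#' @export
binomial_moments_along_path <- function(V_path, N_Na = 6000, N_K = 1800,
                                        init = NULL, dt = NULL,
                                        substeps = 4) {
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
  if (is.null(init)) init <- hh_steady_state(V[1])
  g <- cpp_gating_path(V, dt, init$m, init$h, init$n, as.integer(substeps))
  mean_na <- g$m^3 * g$h
  mean_k <- g$n^4
  data.frame(time_ms = (seq_along(V) - 1) * dt,
             mean_open_Na = mean_na,
             var_open_Na = mean_na * (1 - mean_na) / N_Na,
             mean_open_K = mean_k,
             var_open_K = mean_k * (1 - mean_k) / N_K,
             m = g$m, h = g$h, n = g$n)
}

#' Detect spikes by upward threshold crossing
#'
#' Spike times are linearly interpolated upward crossings of the voltage
#' threshold; crossings within the dead time of the previous accepted spike
#' are discarded.
#'
#' @param trace a `voltage_trace` data frame (columns `time_ms`, `V_mV`) or
#'   numeric voltage vector (then `dt` must be given).
#' @param threshold detection threshold (mV); default -20.
#' @param dead_time minimum separation between spikes (ms); default 2.
#' @param dt grid step when `trace` is a bare vector.
#' @return An object of class `spike_train`: list with `times` (ms),
#'   `threshold`, `dead_time`.
#' @export
detect_spikes <- function(trace, threshold = -20, dead_time = 2, dt = NULL) {
  if (is.data.frame(trace)) {
    tv <- trace$time_ms; V <- trace$V_mV
  } else {
    if (is.null(dt)) stop("dt is required when trace is a bare vector")
    V <- as.numeric(trace); tv <- (seq_along(V) - 1) * dt
  }
  if (any(!is.finite(V))) stop("trace contains non-finite samples")
  up <- which(V[-length(V)] < threshold & V[-1] >= threshold)
  times <- numeric(0)
  last <- -Inf
  for (i in up) {
    tc <- tv[i] + (threshold - V[i]) / (V[i + 1] - V[i]) * (tv[i + 1] - tv[i])
    if (tc - last >= dead_time) {
      times <- c(times, tc)
      last <- tc
    }
  }
  structure(list(times = times, threshold = threshold,
                 dead_time = dead_time), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike_train: %d spikes (threshold %g mV, dead time %g ms)\n",
              length(x$times), x$threshold, x$dead_time))
  invisible(x)
}

#' Interspike-interval statistics with batch standard errors
#'
#' Pools the ISIs of one or more spike trains and reports their mean and
#' coefficient of variation (population-SD convention), with standard
#' errors computed across sequential batches of a fixed number of
#' intervals.
#'
#' @param trains a `spike_train`, a list of them, or a numeric vector of
#'   ISIs (ms).
#' @param spikes_per_batch intervals per batch for the standard errors;
#'   default 50.
#' @return List of class `isi_stats`: `mean_isi`, `cv`, `se_mean`, `se_cv`,
#'   `n_isi`, `n_batches`.  Standard errors are `NA` with fewer than two
#'   batches.
#' @export
isi_stats <- function(trains, spikes_per_batch = 50) {
  isis <- if (is.numeric(trains)) {
    as.numeric(trains)
  } else {
    if (inherits(trains, "spike_train")) trains <- list(trains)
    unlist(lapply(trains, function(tr) diff(tr$times)))
  }
  if (length(isis) < spikes_per_batch)
    stop(sprintf("insufficient data: %d ISIs, need at least %d",
                 length(isis), spikes_per_batch))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  m <- mean(isis)
  cv <- pop_sd(isis) / m
  nb <- floor(length(isis) / spikes_per_batch)
  se_mean <- NA_real_; se_cv <- NA_real_
  if (nb >= 2) {
    idx <- rep(seq_len(nb), each = spikes_per_batch)
    used <- isis[seq_len(nb * spikes_per_batch)]
    bm <- tapply(used, idx, mean)
    bcv <- tapply(used, idx, function(x) pop_sd(x) / mean(x))
    se_mean <- stats::sd(bm) / sqrt(nb)
    se_cv <- stats::sd(bcv) / sqrt(nb)
  }
  structure(list(mean_isi = m, cv = cv, se_mean = se_mean, se_cv = se_cv,
                 n_isi = length(isis), n_batches = nb),
            class = "isi_stats")
}

#' @export
print.isi_stats <- function(x, ...) {
  cat(sprintf("ISI statistics (%d intervals, %d batches)\n", x$n_isi,
              x$n_batches))
  cat(sprintf("  mean = %.3f ms (SE %.3f); CV = %.4f (SE %.4f)\n",
              x$mean_isi, x$se_mean, x$cv, x$se_cv))
  invisible(x)
}

#' Histogram of first-spike times across repeated trials
#'
#' Bins the first spike time after stimulus onset of each contributing
#' trial into left-closed, right-open bins anchored at the onset, and
#' reports the mean and standard error of the counts across batches of
#' trials.
#'
#' @param trains list of `spike_train` objects (one per trial).
#' @param bin bin width (ms); default 0.15.
#' @param window `c(start, end)` of the histogram (ms); trials whose first
#'   spike after `start` falls outside are not binned.
#' @param n_batches number of batches for the standard errors; default 10.
#' @return Data frame with `bin_left_ms`, `mean_count`, `se_count`;
#'   attribute `n_spikes` gives the number of binned spikes.
#' @export
spike_time_histogram <- function(trains, bin = 0.15, window, n_batches = 10) {
  if (bin <= 0) stop("bin must be > 0")
  first <- vapply(trains, function(tr) {
    t <- tr$times[tr$times >= window[1]]
    if (length(t)) t[1] else NA_real_
  }, 0.0)
  first <- first[!is.na(first) & first < window[2]]
  edges <- seq(window[1], window[2] + bin, by = bin)
  nbin <- length(edges) - 1
  if (!length(first)) {
    return(data.frame(bin_left_ms = edges[-length(edges)],
                      mean_count = rep(0, nbin), se_count = rep(NA_real_, nbin)))
  }
  which_bin <- floor((first - window[1]) / bin) + 1
  batch <- rep(seq_len(n_batches), length.out = length(first))
  counts <- matrix(0, n_batches, nbin)
  for (i in seq_along(first))
    counts[batch[i], which_bin[i]] <- counts[batch[i], which_bin[i]] + 1
  out <- data.frame(bin_left_ms = edges[seq_len(nbin)],
                    mean_count = colMeans(counts) * n_batches,
                    se_count = apply(counts, 2, stats::sd) /
                      sqrt(n_batches) * n_batches)
  attr(out, "n_spikes") <- length(first)
  out
}
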