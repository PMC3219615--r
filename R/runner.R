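#' Experiment configuration
#'
#' Validated description of one simulation experiment: a model, a protocol
#' and its parameters, duration/step, replicate count and seed.  Protocols:
#' \describe{
#'   \item{`clamp`}{voltage clamp at `clamp_V` (stochastic channel dynamics
#'     only).}
#'   \item{`replay`}{ensemble replay of a recorded voltage trajectory
#'     (`replay_path`, a CSV trace file, or `replay_trace`, an in-memory
#'     trace).}
#'   \item{`dc`}{free-running membrane under constant current `I_DC`.}
#'   \item{`step`}{free-running membrane, current stepping from 0 to
#'     `I_DC` at `step_time` ms.}
#' }
#'
#' @param model one of the model selectors of [simulate_neuron()].
#' @param protocol `"clamp"`, `"replay"`, `"dc"` or `"step"`.
#' @param T duration (ms).
#' @param dt step (ms).
#' @param reps replicates (clamp/replay protocols).
#' @param seed root integer seed.
#' @param I_DC constant or step current amplitude (uA/cm^2).
#' @param clamp_V clamp voltage (mV).
#' @param step_time step-onset time (ms).
#' @param replay_path path to a trace CSV for the replay protocol.
#' @param replay_trace in-memory `voltage_trace` (alternative to
#'   `replay_path`).
#' @param sigma_I current-noise intensity.
#' @param params a [membrane_params()] or a named list of overrides to the
#'   defaults.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(model, protocol = c("dc", "clamp", "replay",
                                                  "step"),
                              T = 1000, dt = 0.01, reps = 1, seed = 1,
                              I_DC = 0, clamp_V = -65, step_time = 0,
                              replay_path = NULL, replay_trace = NULL,
                              sigma_I = 0, params = list()) {
  model <- match.arg(model, MODEL_CHOICES)
  protocol <- match.arg(protocol)
  if (reps < 1) stop("config field reps: must be >= 1")
  check_time_args(T, dt)
  if (inherits(params, "membrane_params")) params <- unclass(params)
  if (protocol == "replay" && is.null(replay_path) && is.null(replay_trace))
    stop("config field replay_path: required for the replay protocol")
  if (!is.null(replay_path) && !file.exists(replay_path))
    stop("config field replay_path: file not found: ", replay_path)
  structure(list(model = model, protocol = protocol, T = T, dt = dt,
                 reps = as.integer(reps), seed = seed, I_DC = I_DC,
                 clamp_V = clamp_V, step_time = step_time,
                 replay_path = replay_path, replay_trace = replay_trace,
                 sigma_I = sigma_I, params = params),
            class = "experiment_config")
}

config_to_params <- function(config) {
  do.call(membrane_params, config$params)
}

#' Serialize / restore an experiment configuration
#'
#' @param config an [experiment_config()].
#' @param path JSON file path.
#' @return `config_to_json` invisibly returns `path`; `config_from_json`
#'   the restored `experiment_config`.
#' @export
config_to_json <- function(config, path) {
  x <- unclass(config)
  x$replay_trace <- NULL
  jsonlite::write_json(x[!vapply(x, is.null, TRUE)], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname config_to_json
#' @export
config_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(experiment_config, x)
}

run_protocol_current <- function(config) {
  if (config$protocol == "dc") {
    config$I_DC
  } else {
    function(t) if (t >= config$step_time) config$I_DC else 0
  }
}

#' Run one experiment and write its outputs
#'
#' Dispatches to the right simulator/protocol, writes the resulting trace
#' or ensemble statistics (and spike times for free-running protocols) as
#' CSV, and records a manifest (config, root seed, per-replicate
#' sub-seeds, output inventory, file checksums).  Re-running the same
#' config and seed reproduces the data files byte-identically.
#'
#' @param config an [experiment_config()].
#' @param outdir output directory (created if missing).
#' @param quiet suppress progress messages.
#' @return The manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_experiment <- function(config, outdir, quiet = FALSE) {
  if (!inherits(config, "experiment_config"))
    stop("config must be an experiment_config")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  params <- config_to_params(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  files <- character(0)
  sub_seeds <- NULL

  if (config$protocol %in% c("dc", "step")) {
    say("run_experiment: %s / %s, T = %g ms", config$model, config$protocol,
        config$T)
    tr <- simulate_neuron(config$model, params, I = run_protocol_current(config),
                          T = config$T, dt = config$dt,
                          seed = if (config$model == "deterministic") NULL
                                 else config$seed,
                          sigma_I = config$sigma_I)
    f <- file.path(outdir, "trace.csv")
    write_voltage_trace(tr, f)
    files <- c(files, f)
    st <- detect_spikes(tr)
    f <- file.path(outdir, "spikes.csv")
    write.csv(data.frame(spike_time_ms = st$times), f, row.names = FALSE)
    files <- c(files, f)
  } else {
    V_path <- if (config$protocol == "clamp") {
      rep(config$clamp_V, round(config$T / config$dt) + 1)
    } else if (!is.null(config$replay_trace)) {
      config$replay_trace
    } else {
      read_voltage_trace(config$replay_path)
    }
    if (config$model == "deterministic") {
      mom <- binomial_moments_along_path(V_path, params$N_Na, params$N_K,
                                         dt = config$dt)
      f <- file.path(outdir, "moments.csv")
      write.csv(mom, f, row.names = FALSE)
      files <- c(files, f)
    } else {
      say("run_experiment: %s / %s, reps = %d", config$model,
          config$protocol, config$reps)
      es <- replay_ensemble(config$model, V_path, reps = config$reps,
                            seed = config$seed, params = params,
                            dt = config$dt)
      f <- file.path(outdir, "ensemble.csv")
      write_ensemble_stats(es, f)
      files <- c(files, f)
      sub_seeds <- vapply(seq_len(min(config$reps, 64)) - 1,
                          function(k) cpp_substream(config$seed, k), 0.0)
    }
  }
  cfg_file <- file.path(outdir, "config.json")
  config_to_json(config, cfg_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("hhnoise")),
    config_file = basename(cfg_file),
    config_hash = unname(tools::md5sum(cfg_file)),
    root_seed = config$seed,
    sub_seeds = sub_seeds,
    created = format(Sys.time(), tz = "UTC"),
    outputs = data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Run several models under an identical protocol
#'
#' Runs each model with the same protocol, conditions and root seed and
#' returns a tidy long-format table of summary statistics: for `dc`, the
#' ISI mean/CV with batch standard errors per drive level; for `replay`,
#' the integrated squared deviation of each model's ensemble variance from
#' the closed-form binomial variance along the path.
#'
#' @param models character vector of model selectors (>= 1).
#' @param protocol `"dc"` or `"replay"`.
#' @param config shared [experiment_config()] (its `model` field is
#'   ignored).
#' @param I_levels for `dc`: vector of DC amplitudes (defaults to
#'   `config$I_DC`).
#' @param n_spikes for `dc`: spikes collected per model and level.
#' @param quiet suppress progress messages.
#' @return A long-format data frame.
#' @export
run_comparison <- function(models, protocol = c("dc", "replay"), config,
                           I_levels = NULL, n_spikes = 500, quiet = FALSE) {
  protocol <- match.arg(protocol)
  if (length(models) < 1) stop("at least one model is required")
  params <- config_to_params(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  if (protocol == "dc") {
    if (is.null(I_levels)) I_levels <- config$I_DC
    rows <- list()
    for (I in I_levels) for (mod in models) {
      say("run_comparison: %s at I = %g", mod, I)
      st <- collect_spike_trains(mod, params, I, config$dt, config$seed,
                                 n_spikes = n_spikes,
                                 sigma_I = config$sigma_I)
      s <- isi_stats(st)
      rows[[length(rows) + 1]] <-
        data.frame(model = mod, I_DC = I, statistic = c("mean_isi", "cv"),
                   value = c(s$mean_isi, s$cv), se = c(s$se_mean, s$se_cv))
    }
    do.call(rbind, rows)
  } else {
    V_path <- if (!is.null(config$replay_trace)) config$replay_trace
              else read_voltage_trace(config$replay_path)
    mom <- binomial_moments_along_path(V_path, params$N_Na, params$N_K,
                                       dt = config$dt)
    rows <- list()
    for (mod in models) {
      say("run_comparison: replay %s", mod)
      es <- replay_ensemble(mod, V_path, reps = config$reps,
                            seed = config$seed, params = params,
                            dt = config$dt)
      err_na <- mean((es$var_open_Na - mom$var_open_Na)^2)
      err_k <- mean((es$var_open_K - mom$var_open_K)^2)
      rows[[length(rows) + 1]] <-
        data.frame(model = mod, statistic = c("var_mse_Na", "var_mse_K"),
                   value = c(err_na, err_k), se = NA_real_)
    }
    do.call(rbind, rows)
  }
}

#' Generate a spontaneous-spike voltage path from the Markov-chain model
#'
#' Canned protocol for the replayed-trajectory comparison: simulates the
#' Markov-chain neuron with no applied current until a channel-noise-induced
#' spike preceded by a quiet subthreshold stretch is found, and returns the
#' window around it (by default 120 ms before to 40 ms after the upward
#' threshold crossing), re-anchored at time 0.
#'
#' @param params a [membrane_params()].
#' @param seed integer seed.
#' @param pre,post window extent before/after the spike (ms).
#' @param dt time step (ms).
#' @param max_T give up after this much simulated time (ms).
#' @return A `voltage_trace` data frame with attribute `spike_time` (ms,
#'   relative to the window start).
#' @export
spontaneous_spike_path <- function(params = membrane_params(), seed = 1,
                                   pre = 120, post = 40, dt = 0.01,
                                   max_T = 20000) {
  chunk_T <- 2000
  n_chunks <- ceiling(max_T / chunk_T)
  for (k in seq_len(n_chunks)) {
    tr <- simulate_neuron("markov", params, I = 0, T = chunk_T, dt = dt,
                          seed = cpp_substream(seed, k))
    st <- detect_spikes(tr)
    times <- st$times
    for (ts in times) {
      quiet <- !any(times > ts - pre - 5 & times < ts)
      if (ts > pre && ts < chunk_T - post && quiet) {
        i0 <- which(tr$time_ms >= ts - pre)[1]
        i1 <- which(tr$time_ms >= ts + post)[1]
        path <- tr[i0:i1, c("time_ms", "V_mV")]
        path$time_ms <- round(path$time_ms - tr$time_ms[i0], 10)
        rownames(path) <- NULL
        class(path) <- c("voltage_trace", "data.frame")
        attr(path, "dt") <- dt
        attr(path, "spike_time") <- ts - tr$time_ms[i0]
        return(path)
      }
    }
  }
  stop("no isolated spontaneous spike found within max_T")
}

# accumulate spike trains from repeated chunks until n_spikes are available
collect_spike_trains <- function(model, params, I, dt, seed, n_spikes = 500,
                                 chunk_T = 2000, max_T = 120000,
                                 sigma_I = 0, threshold = -20,
                                 dead_time = 2) {
  trains <- list()
  total <- 0; total_T <- 0; k <- 0
  rest <- resting_state(params)
  while (total < n_spikes + 1 && total_T < max_T) {
    k <- k + 1
    tr <- simulate_neuron(model, params, I = I, T = chunk_T, dt = dt,
                          seed = cpp_substream(seed, k), init = rest,
                          sigma_I = sigma_I)
    st <- detect_spikes(tr, threshold, dead_time)
    trains[[k]] <- st
    total <- total + length(st$times)
    total_T <- total_T + chunk_T
  }
  trains
}
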