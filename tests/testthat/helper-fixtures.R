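# Shared fixtures, built once per test session and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

fix_params <- function() memo("params", membrane_params())

# Markov-chain spontaneous-spike voltage path (no applied current),
# 120 ms subthreshold + spike + 40 ms tail
fig1_path <- function() memo("fig1_path",
  spontaneous_spike_path(fix_params(), seed = 3))

# replay ensembles on the shared path, keyed by model and replicate count;
# the system-size model integrates at dt/2 so that its O(dt) stationary
# bias stays below the Monte-Carlo resolution of the comparisons
fig1_replay <- function(model, reps, seed = 9) {
  memo(sprintf("replay_%s_%d_%d", model, reps, seed),
       replay_ensemble(model, fig1_path(), reps = reps, seed = seed,
                       params = fix_params(),
                       substeps = if (model == "ssa") 2 else 1))
}

fig1_moments <- function() memo("fig1_moments", {
  p <- fix_params()
  binomial_moments_along_path(fig1_path(), p$N_Na, p$N_K)
})

# analysis windows on the shared path: burn-in discarded; subthreshold
# window ends 5 ms before the spike; spike window brackets the upstroke
fig1_windows <- function() {
  path <- fig1_path()
  tsp <- attr(path, "spike_time")
  list(spike_time = tsp,
       analysis = path$time_ms > 30,
       subthr = path$time_ms > 30 & path$time_ms < tsp - 5,
       spike = path$time_ms > tsp - 0.5 & path$time_ms < tsp + 2)
}

# ISI statistics at the reference DC drive, keyed by model
isi_reference <- function(model, I = 7, n_spikes = 500, seed = 21,
                          sigma_I = 0) {
  memo(sprintf("isi_%s_%g_%d_%g", model, I, n_spikes, sigma_I), {
    trains <- hhnoise:::collect_spike_trains(model, fix_params(), I = I,
                                             dt = 0.01, seed = seed,
                                             n_spikes = n_spikes,
                                             sigma_I = sigma_I)
    isi_stats(trains)
  })
}

# combined standard error of a difference
se2 <- function(a, b) sqrt(a^2 + b^2)
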